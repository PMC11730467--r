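Package: coashift
Title: Centre-of-Abundance Shift Rates and Migratory Flocking in North American Birds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline linking migratory flocking behaviour to
    long-term shifts in seasonal centres of abundance (COA) of North American
    migratory birds. Computes abundance-weighted annual centres of abundance from
    stratum-level survey index posteriors with first-order Taylor error
    propagation, estimates per-axis linear COA trends and the combined
    displacement vector in metres per year, classifies species as mixed-age or
    age-separated autumn migrants from banding records via penalized-spline
    latitude-by-day curves and a normalised area-under-curve overlap index,
    assembles species trait tables, and fits measurement-error phylogenetic
    generalised least squares models with variance-inflation filtering,
    all-subsets AICc candidate enumeration and model averaging. A synthetic-data
    module generates every pipeline input with known ground truth (drifting
    abundance surfaces, age-structured banding phenologies, Brownian traits on a
    simulated phylogeny, planted flocking effects) so the whole analysis is
    testable end to end without survey downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
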