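# coashift

Does migrating in flocks help bird species track a changing climate? Species
whose juveniles migrate alongside experienced adults can, in principle,
transmit novel migration routes socially, letting their ranges shift faster
than species whose young must rely on inherited programmes. `coashift`
implements the full analysis pipeline needed to test that hypothesis with
North American survey data, and a synthetic-data module that makes every
stage verifiable against planted ground truth.

The pipeline has four stages:

1. **Centres of abundance (COA).** For each species, season and year, the
   COA is the abundance-weighted mean of survey-stratum centroids,

   $$COA = \frac{\sum_s I_s x_s}{\sum_s I_s},$$

   where $I_s$ is the posterior median abundance index of stratum $s$ and
   $x_s$ its centroid longitude or latitude. Posterior SDs are recovered
   from 95th-percentile bounds as $(hi - lo)/3.92$ and propagated through
   the weighted mean, the per-axis OLS trend on year, and the Pythagorean
   combination $d = \sqrt{a^2 + b^2}$ (metres/year, longitude
   cosine-corrected at the species' mean COA latitude) by the first-order
   Taylor method.

2. **Cohort timing.** Hatch-year (HY) and after-hatch-year (AHY) banding
   records yield per-age-class latitude-by-day penalized spline curves
   (about 10 basis functions, GCV smoothing). Within the autumn window the
   curves are min–max normalised and compared by the proportional
   area-under-curve overlap $\int\min(\hat f_{HY}, \hat f_{AHY}) /
   \int\max(\hat f_{HY}, \hat f_{AHY})$; species with overlap > 0.85 are
   classed as mixed-age migrants, otherwise age-separated.

3. **Trait assembly.** Flocking classifications (maximum travelling flock
   size > 2; sensitivity thresholds 5 and 10; small/large flock categories),
   great-circle migration distance, absolute population trend, and the
   remaining covariates are merged with the COA shifts and Z-scored.

4. **Phylogenetic inference.** The shift rate is modelled by generalized
   least squares with residual covariance $\sigma^2 C + \mathrm{diag}(SE^2)$
   — $C$ the Brownian correlation from the phylogeny, $SE$ the propagated
   shift-rate errors (reciprocal-SE weighting). Predictors pass a stepwise
   VIF filter (cutoff 5), all nested candidate models are enumerated
   (excluding any with fewer than 10 observations per predictor column), and
   candidates within 2 AICc units of the best are averaged with Akaike
   weights; terms whose 95% CI excludes zero are flagged significant.

## Worked example

Simulate a non-breeding index series whose abundance surface drifts
north-east at a planted 1000 m/yr east + 3000 m/yr north (speed
$\sqrt{1000^2 + 3000^2} \approx 3162$ m/yr), and recover the shift:

```r
library(coashift)
scn <- sim_scenario(true_velocity = c(east = 1000, north = 3000), seed = 42)
idx <- simulate_index_series(scn, "Setophaga synthetica", season = "nonbreeding")
species_shift(idx)$shift
#>                species      season trend_lat trend_lon displacement_m displacement_se_m
#> 1 Setophaga synthetica nonbreeding   0.02708   0.01193           3179             71.65
```

The estimated displacement (3179 ± 72 m/yr) matches the planted 3162 m/yr
within one standard error; the per-axis trends are in degrees/year.

Classify cohort timing from synthetic banding records of a species whose
juveniles and adults pass concurrently (`cohort_separation = 0`):

```r
band <- simulate_banding(sim_scenario(cohort_separation = 0, seed = 42),
                         "Setophaga synthetica")
cohort_overlap(band)
#>                species window_start window_end overlap_index n_hy n_ahy classification
#> 1 Setophaga synthetica          242        313          0.86 1313  1323      mixed_age
```

The detected autumn window spans days 242–313 and the age-class curves
overlap at 0.86 > 0.85, so the species is classed as a mixed-age migrant.

Fit the trait models on a simulated 81-species pool with the default planted
effects (mixed-age flocks +2661 m/yr, age-separated +798, night migration
−1276, migration distance +723 per SD):

```r
tree <- simulate_tree(81, seed = 42)
tr <- simulate_traits(tree, sim_scenario(n_species = 81, seed = 42))
tab <- zscore_columns(tr$traits, c("migration_distance_km", "generation_length_yr"))
m <- fit_trait_models(tab, tree,
                      predictors = c("flocking_behaviour", "migratory_timing",
                                     "migration_distance_km", "generation_length_yr"))
tidy(m$average)
#>   term                           estimate std.error conf.low conf.high significant
#> 1 (Intercept)                       1820.      389.   1058.      2582. TRUE
#> 2 flocking_behaviourage_separated    461.      272.    -72.2      995. FALSE
#> 3 flocking_behaviourmixed_age       2439.      202.   2043.      2836. TRUE
#> 4 migratory_timingnight             -927.      191.  -1300.      -553. TRUE
#> 5 migration_distance_km              734.      160.    421.      1047. TRUE

m$marginal_means
#>           level mean    se
#> 1          solo 1814 391.8
#> 2 age_separated 2266 421.7
#> 3     mixed_age 4220 404.3
```

The model-averaged mixed-age coefficient (2439 ± 202 m/yr, CI excluding
zero) recovers the planted effect; adjusted mean shift rates per flocking
class show mixed-age flocking species shifting fastest, as planted.

`simulate_inputs()` writes a complete input set (stratum indices, banding,
traits, Newick tree, ground-truth JSON) and `run_pipeline()` executes all
four stages end to end, producing per-season Model A (binary flocking) and
Model B (three-level flocking behaviour) outputs. A thin command-line
wrapper lives at `inst/cli/coashift.R`.

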