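---
title: "Methods: centre-of-abundance shifts, cohort timing, and phylogenetic inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: centre-of-abundance shifts, cohort timing, and phylogenetic inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`coashift` estimates how fast the seasonal centres of abundance (COA) of
North American migratory birds have shifted, classifies each species'
migratory flocking behaviour, and asks — with phylogenetic comparative
methods — whether socially migrating species shift faster. This vignette is
the package's own account of the models, the tunable parameters, the
numerical choices, and what the synthetic-data experiments do and do not
demonstrate.

## 1. The centre-of-abundance model

The survey inputs are stratum-level annual abundance index posteriors: for
each species, season (breeding or non-breeding), spatial stratum and year, a
posterior median $I_s$ with 95th-percentile bounds. Strata enter only
through their centroid coordinates; their polygon geometry is irrelevant to
every quantity computed here.

For one species, season and year the COA is the abundance-weighted mean of
stratum centroids, computed separately per axis:

$$COA = \frac{\sum_s I_s\, x_s}{\sum_s I_s}.$$

This statistic is invariant to rescaling all indices by a positive constant
and always lies within the range of contributing centroids. Years in which
every index is zero have no defined COA; they are flagged and excluded from
trend fitting rather than imputed (the slope estimator needs no balanced
panel).

**Uncertainty.** Posterior SDs are recovered from the percentile bounds as
$SD = (hi_{95} - lo_{95})/3.92$ (normal approximation) and propagated by the
first-order Taylor (delta) method. Since
$\partial COA/\partial I_s = (x_s - COA)/\sum I$, the COA variance is
$\sum_s SD_s^2\,\big((x_s - COA)/\sum I\big)^2$, treating stratum posteriors
as independent. The upstream hierarchical survey models induce cross-stratum
posterior correlation that their published outputs do not expose; ignoring
it is a documented limitation, not an oversight.

**Trends and displacement.** The per-axis trend is the OLS slope of COA on
year. The slope is linear in the COAs,
$b = \sum_n w_n\,COA_n$ with $w_n = (t_n - \bar t)/\sum (t - \bar t)^2$, so
the propagated variance is exactly $\sum_n w_n^2\,\mathrm{Var}(COA_n)$. The
two axis trends are converted to metres/year (111 320 m per degree latitude;
longitude additionally scaled by the cosine of the species' mean COA
latitude — a fixed reference latitude is available as a sensitivity setting)
and combined as $d = \sqrt{a^2 + b^2}$ with delta-method variance
$(a^2 \mathrm{Var}(a) + b^2 \mathrm{Var}(b))/d^2$; at $d = 0$ the SE falls
back to $\sqrt{\mathrm{Var}(a) + \mathrm{Var}(b)}$. Covariance between the
axis trends is ignored, matching the per-axis presentation of the source
analyses. The reciprocal of the displacement SE becomes the species' weight
in the trait models.

Because $d$ is a magnitude, it is biased upward when the true displacement
is small relative to its SE (a folded-normal effect); the recovery
experiments plant drifts large relative to their SEs, where the bias is
negligible.

## 2. Cohort timing from banding records

Species that migrate in flocks may move as mixed-age flocks (juveniles
travelling with experienced adults — the configuration that permits social
route transmission) or as age-separated cohorts. The package quantifies this
from banding records: as autumn migration proceeds, the latitude of banding
events declines, and if hatch-year (HY) birds pass later than
after-hatch-year (AHY) birds, the two latitude-by-day curves separate.

Per age class, a penalized thin-plate regression spline of latitude on
Julian day is fitted with `mgcv` (basis dimension 10, smoothness by
generalized cross-validation) and evaluated on a shared integer day grid.
Species need at least 1 000 records in total — applied to the full record
set, since the windowed subset of a strongly age-separated species is
legitimately smaller — and 30 per age class inside the autumn window;
shortfalls yield an `insufficient_data` classification, never an error.

**Autumn window.** The source procedure picked the window visually; any
automation is therefore a design decision. The package uses a
descent-interval rule on the pooled (both ages) curve: the window runs from
the last day still within 0.5° of the pre-migration maximum to the first
subsequent day within 0.5° of the post-migration minimum, requiring a total
decline of at least 2° and a mean slope below −0.005°/day. A
longest-monotone-run rule was rejected because the pooled curve of an
age-separated species genuinely *rises* between the two passage waves (the
age-class mixture shifts towards not-yet-departed juveniles), splitting the
window in half. A manual window override is accepted.

**Overlap index.** Within the window each curve is min–max normalised to
$[0,1]$ (absorbing affine transforms of either raw curve) and compared by
proportional area-under-curve overlap,
$\int \min(\hat f_{HY}, \hat f_{AHY}) \,/\, \int \max(\hat f_{HY}, \hat f_{AHY})$.
The integrals are exact for piecewise-linear curves: segments are split at
crossing points rather than trapezoid-ruled across them, so the index can be
validated against a fine-grid integrator at $10^{-6}$. The alternative
normalisation $\int\min / \mathrm{mean}(\int \hat f_A, \int \hat f_B)$ is
available as a configuration switch. Overlap strictly greater than 0.85
classifies the species as a mixed-age migrant (the boundary value itself is
age-separated); 0.85 is the conventional calibration of this procedure
against literature-derived labels. Day-of-year wraparound (Dec–Jan
migration) is not handled; autumn windows sit within one calendar year.

## 3. Trait assembly

Maximum travelling flock size > 2 defines a flocking species (strict
inequality; 5 and 10 are the standard sensitivity thresholds, and the
solo/small/large categorisation splits at 2 and 10, assigning the ambiguous
value 10 to "large"). Binary flocking combines with cohort timing into the
three-level behaviour factor (solo dominates; unresolved cohort timing
propagates as `insufficient_data`, excluding the species from the
three-level Model B pool while retaining it in the binary Model A pool — so
the A pool always nests B). Migration distance is the haversine distance
between seasonal range centroids on a sphere of radius 6 371.0088 km;
population trends enter as absolute values; continuous predictors are
Z-scored with the sample-SD convention, and the recorded means/SDs allow
coefficients to be back-transformed to original units. Standardization
happens once, before VIF filtering. Missing predictor values exclude a
species with a logged tally; no imputation from congeners is attempted.

## 4. Phylogenetic inference with response measurement error

The response (displacement, m/yr) carries a known per-species SE. The model
is generalized least squares with residual covariance

$$V = \sigma^2 C + \mathrm{diag}(SE^2),$$

where $C$ is the Brownian-motion correlation implied by the consensus
phylogeny (shared root-to-MRCA path length, unit diagonal after scaling by
tree depth; non-ultrametric trees are scaled by per-tip depths with a
warning) and $\sigma^2$ is the residual Brownian rate, profiled by
one-dimensional optimisation. This additive measurement-error form is the
standard reading of reciprocal-SE weighting in phylogenetic regression; a
pure weights-only GLS ($V = \sigma^2\,\mathrm{diag}(SE^2)$, no phylogenetic
term) is available for sensitivity. With a star phylogeny and zero SEs the
estimator reduces exactly to OLS.

**REML vs ML.** Coefficient inference uses the REML profile of $\sigma^2$ by
default: in simulation, ML-based Wald intervals undercover (the ML rate is
biased low and the interval ignores its uncertainty), while REML restores
near-nominal coverage — and REML is the default of the measurement-error
PGLS routines used in this literature. Log-likelihoods and AICc reported for
model ranking are always the ML values, because restricted likelihoods are
not comparable across fixed-effect structures. $k$ counts the intercept,
predictors and $\sigma^2$; $AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)$.

**Confidence intervals** on individual fits use the t distribution with
$n - p$ degrees of freedom, the convention of the GLS implementations this
literature builds on; in simulation the normal multiplier undercovers by
about half a point even at $n = 100$, and Wald intervals already sit
slightly below nominal because the profiled $\sigma^2$ is treated as known.
Model-averaged intervals use the standard $\pm 1.96\,SE$ form of the
zero-substituted averaging literature (degrees of freedom are ill-defined
across a candidate set). Calibration experiments are sized at $n = 100$ for
the Brownian planted-effect check and $n = 81$ for the end-to-end
null/power check.

**VIF filtering** regresses each design column on the others and removes,
one term at a time, the term owning the largest $VIF = 1/(1-R^2)$ above 5
(factor dummy blocks leave whole; exact ties resolve to the later column)
until all columns pass. **Candidate models** are all subsets of the filtered
terms (intercept always present, factors entering whole); subsets with fewer
than 10 observations per predictor column are excluded to limit overfitting,
and enumeration refuses beyond 20 terms. **Model averaging** retains
candidates within 2 AICc units of the best, renormalises Akaike weights
$w_i \propto e^{-\Delta_i/2}$ over the retained set, and averages
coefficients with full (zero-substituted) averaging by default — a term
absent from a candidate contributes 0 with zero variance — using the
standard unconditional SE
$\sum_i w_i \sqrt{se_i^2 + (\hat\beta_i - \bar\beta)^2}$; conditional
averaging is available. Treatment contrasts use "solo" as the reference
level, so flocking coefficients read as increments over solo migrants.
Significance is a 95% CI excluding zero; z-based p-values are reported with
that convention flagged.

Zero-substituted averaging deliberately shrinks towards zero, so its
significance flag is conservative rather than a nominal-5% test. The
package's null-calibration experiment therefore measures the false-positive
rate on the global-model Wald interval — the only statistic with a nominal
level — and separately confirms that the averaged flag is never
anticonservative relative to it.

## 5. The synthetic-data generator

Every pipeline input can be generated with known ground truth
(`sim_scenario()` + `simulate_*()`), which is what makes the chain testable
without survey downloads. The generator's defaults describe the study
conditions the package targets:

* **Index series.** A bivariate Gaussian abundance surface (SD 3°) on a
  12 × 12 stratum grid spanning 40° × 40°, 1970–2019, drifting at the
  planted velocity, total mass following the population trend (0.5 %/yr),
  with independent multiplicative lognormal noise (sdlog 0.1) per
  stratum-year and 95% bounds $median \cdot e^{\pm 1.96\,cv}$ with
  $cv = 0.1$. The CI width factor is matched to the noise scale because
  interval coverage is only a meaningful property when the stated
  uncertainty equals the generating uncertainty. The noiseless-recovery
  experiments demonstrate that grid discretisation contributes error well
  under 1% when the surface stays 2 SD inside the grid (the generator
  refuses scenarios that drift closer to the edge).
* **Banding records.** Per age class, banding days are normal around the
  class passage day (AHY day 260; HY shifted by the cohort separation) with
  three times the 5-day passage spread, and expected latitude declines
  sigmoidally from 45° to 30° as passage progresses, plus 1.5° noise. 3 000
  records per species by default.
* **Phylogeny and traits.** A Yule tree rescaled to unit depth; continuous
  covariates evolve as Brownian motion; flocking behaviour and migratory
  timing evolve as equal-rates Markov processes along branches
  (phylogenetically clumped; scenarios are conditioned on all three classes
  being realised). The true shift rate is
  baseline (2 000 m/yr) + flocking-class effect + covariate effects +
  Brownian residual (SD 1 500 m/yr over unit depth), and the observed shift
  adds normal error with per-species SE drawn lognormal (median 600 m/yr) —
  exactly the generative model the measurement-error PGLS assumes. Default
  planted effects (mixed-age +2 660.87, age-separated +797.5, night
  −1 276.23, distance +723.43 m/yr per SD) are the magnitudes characteristic
  of published COA analyses of this system, so power experiments run at
  realistic effect sizes; residual and measurement scales were chosen so the
  implied coefficient SE (≈ 440 m/yr at n = 81) matches that literature.

**What passing synthetic tests does not show.** The generator omits observer
effort and detectability structure, spatially correlated index errors,
route-level variation below the stratum, sex-structured timing, and
real-range geometry. Recovery and calibration results therefore validate
the estimators under their stated assumptions; they do not certify the
upstream survey models, and displacement estimates for species whose ranges
barely intersect the survey region inherit the boundary biases discussed
for the COA statistic.

## 6. Numerical choices and degenerate inputs

* Taylor-propagated SEs are validated against $10^5$-draw Monte-Carlo SDs at
  2% relative tolerance; index draws are truncated at zero. Instance CVs are
  capped at 0.12 so the $O(cv^2)$ first-order truncation error stays clearly
  inside the comparison band (at cv 0.15 it approaches 1.9%).
* $\sigma^2$ is profiled on $[0, 100\,\mathrm{var}(y)]$ (lower bound
  $10^{-10}\mathrm{var}(y)$ when any SE is zero, keeping $V$ positive
  definite) with boundary checking; singular designs and all-zero-index
  years raise informative errors.
* Constant curves cannot be min–max normalised and raise a degenerate-curve
  error; all-zero overlap denominators return 0.
* Ties: VIF removal resolves exact ties to the later column; flock-size 10
  is "large"; overlap exactly 0.85 is age-separated; threshold rules use
  strict inequalities throughout.
* Invalid banding rows are dropped with a logged tally (opportunistic data),
  while malformed index tables error loudly (model outputs should never be
  silently repaired).

## 7. Orchestration

`simulate_inputs()` writes the full input set (CSVs, Newick, scenario YAML,
ground-truth JSON); `run_pipeline()` executes COA → cohort timing → assembly
→ PGLS for each season and both model variants (A: binary flocking; B:
three-level behaviour on the resolved-timing subset), writing per-stage CSV/
JSON outputs plus a manifest recording the seed, configuration and input
digests. All generators are seed-deterministic (identical scenario + seed ⇒
identical files). The package's interface is its functions; a thin
command-line wrapper (`inst/cli/coashift.R`) exposes `simulate` and
`run-all` for shell use. Content-addressed caching and automatic no-op
reruns were considered and left out as disproportionate for an analysis
package; the manifest makes reruns auditable instead.

Problem sizes used by the validation suite — 200 drift-recovery replicates,
2 000 Brownian-calibration replicates at $n = 100$ (each on a fresh
simulated tree, so replicates are independent and the Monte-Carlo SE on the
coverage estimate is about half a point), 100 synthetic species for cohort
classification, and 200 + 200 null/power replicates at $n = 81$ — are the
package's chosen compromise between Monte-Carlo resolution and a validation
suite that runs in minutes on one CPU.

## 8. Known limitations

* Cross-stratum and lat–lon trend covariances are ignored in propagation.
* The displacement magnitude is upward-biased near zero true drift.
* Brownian motion is the only residual correlation structure (no Pagel's λ
  or OU), and a single consensus tree is used, matching the scope of the
  source analyses.
* The 0.85 overlap threshold is consumed as a given calibration; the
  package does not re-derive it from literature labels.
* Autumn-window automation, while robust to age-separated phenologies, can
  still be confounded by strongly multimodal passage curves; the manual
  override exists for exactly those species.
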