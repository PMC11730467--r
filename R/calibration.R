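#' Planted-drift recovery experiment
#'
#' Repeatedly simulates a stratum-index series whose abundance surface drifts
#' at a known velocity, runs the full COA stage, and returns the estimated
#' displacement and its propagated SE per replicate — the package's check
#' that the COA estimator is unbiased and its uncertainty well calibrated.
#'
#' @param n_reps Number of replicates.
#' @param velocity Planted drift, `c(east = , north = )` metres/year.
#' @param seed Master seed; replicate r uses a deterministic sub-seed.
#' @param scenario Base [sim_scenario()] whose noise settings define the
#'   replicate conditions (velocity and seed are overridden per replicate).
#' @return A tibble with one row per replicate: `displacement_m`,
#'   `displacement_se_m`, `trend_lat`, `trend_lon`, `covered` (whether the
#'   1.96 SE interval contains the planted speed).
#' @export
shift_recovery_experiment <- function(n_reps, velocity = c(east = 0, north = 5000),
                                      seed = 1L,
                                      scenario = sim_scenario()) {
  truth <- sqrt(sum(velocity^2))
  purrr::map(seq_len(n_reps), function(r) {
    scn <- scenario
    scn$true_velocity <- velocity
    scn$seed <- sub_seed(seed, paste0("recovery", r))
    sh <- species_shift(simulate_index_series(scn, "sp"))$shift
    tibble(rep = r, displacement_m = sh$displacement_m,
           displacement_se_m = sh$displacement_se_m,
           trend_lat = sh$trend_lat, trend_lon = sh$trend_lon,
           covered = abs(sh$displacement_m - truth) <=
             1.96 * sh$displacement_se_m)
  }) %>% bind_rows()
}

#' Null and power calibration of the flocking inference
#'
#' Repeatedly simulates a phylogeny, Brownian traits and a shift-rate
#' response with the given planted flocking-class effects, runs the trait
#' modelling stage (VIF filter, candidate enumeration, measurement-error
#' PGLS, AICc averaging), and records the mixed-age flocking coefficient.
#' With all effects zero this measures the false-positive rate of the
#' global-model Wald interval (the nominal-5% test); with the planted
#' mixed-age effect it measures detection power. The model-averaged
#' significance flag is also recorded; full zero-substituted averaging
#' shrinks towards zero, so its flag is conservative relative to the Wald
#' test.
#'
#' @param n_reps Number of replicate data sets.
#' @param effects Named flocking effects (m/yr) for `solo`, `age_separated`,
#'   `mixed_age`.
#' @param n_species Species pool size per replicate (default 81).
#' @param seed Master seed.
#' @param predictors Predictor terms for the global model.
#' @return A tibble with one row per replicate: `estimate`, `std.error`,
#'   `significant` (global-fit Wald CI excludes zero), `avg_estimate`,
#'   `avg_significant` (model-averaged CI excludes zero).
#' @export
flocking_calibration_experiment <- function(n_reps, effects,
                                            n_species = 81L, seed = 1L,
                                            predictors = c("flocking_behaviour",
                                                           "migratory_timing",
                                                           "migration_distance_km",
                                                           "generation_length_yr")) {
  purrr::map(seq_len(n_reps), function(r) {
    rs <- sub_seed(seed, paste0("calib", r))
    scn <- sim_scenario(n_species = n_species, flocking_effects = effects,
                        seed = rs)
    tree <- simulate_tree(n_species, seed = sub_seed(rs, "tree"))
    tr <- simulate_traits(tree, scn)
    tab <- tr$traits
    tab$abs_population_trend <- absolute_trend(tab$population_trend)
    cont <- intersect(predictors, c("migration_distance_km",
                                    "generation_length_yr",
                                    "abs_population_trend"))
    if (length(cont) > 0) tab <- zscore_columns(tab, cont)
    m <- fit_trait_models(tab, tree, predictors = predictors)
    td <- tidy(m$global)
    row <- td[td$term == "flocking_behaviourmixed_age", ]
    av <- m$average$coefficients
    av_row <- av[av$term == "flocking_behaviourmixed_age", ]
    tibble(
      rep = r, estimate = row$estimate, std.error = row$std.error,
      significant = row$conf.low > 0 | row$conf.high < 0,
      avg_estimate = if (nrow(av_row)) av_row$estimate else 0,
      avg_significant = if (nrow(av_row)) av_row$significant else FALSE
    )
  }) %>% bind_rows()
}
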