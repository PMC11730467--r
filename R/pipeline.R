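#' Write a complete synthetic input set
#'
#' Materialises every pipeline input for a scenario: stratum-index CSVs for
#' both seasons (each species drifting at its planted true shift rate,
#' northward), a banding CSV whose cohort separation follows each species'
#' planted flocking behaviour (0 days for mixed-age flocks, 40 days for
#' age-separated flocks and solo migrants), the trait CSV, the Newick tree,
#' the scenario as YAML, and a ground-truth JSON (planted velocities and
#' effects) for test harnesses.
#'
#' @param scenario A [sim_scenario()].
#' @param dir Output directory (created if needed).
#' @param seasons Seasons to simulate index series for.
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_inputs <- function(scenario, dir,
                            seasons = c("breeding", "nonbreeding")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_tree(scenario$n_species, seed = sub_seed(scenario$seed, "tree"))
  tr <- simulate_traits(tree, scenario)

  sep_for <- function(beh) if (beh == "mixed_age") 0 else 40
  idx <- purrr::map(tree$tip.label, function(sp) {
    v <- c(east = 0, north = unname(tr$truth$true_shift[sp]))
    purrr::map(seasons, function(se) {
      simulate_index_series(scenario, sp, season = se, velocity = v)
    }) %>% bind_rows()
  }) %>% bind_rows()
  band <- purrr::map(tree$tip.label, function(sp) {
    scn_sp <- scenario
    scn_sp$cohort_separation <- sep_for(tr$truth$behaviour[[sp]])
    simulate_banding(scn_sp, sp)
  }) %>% bind_rows()

  paths <- list(
    indices = file.path(dir, "stratum_indices.csv"),
    banding = file.path(dir, "banding.csv"),
    traits = file.path(dir, "traits.csv"),
    tree = file.path(dir, "tree.nwk"),
    scenario = file.path(dir, "scenario.yaml"),
    truth = file.path(dir, "truth.json")
  )
  write_stratum_indices(idx, paths$indices)
  write_banding(band, paths$banding)
  readr::write_csv(tr$traits, paths$traits)
  write_tree(tree, paths$tree)
  yaml::write_yaml(lapply(unclass(scenario), unname), paths$scenario)
  jsonlite::write_json(
    list(true_shift = as.list(tr$truth$true_shift),
         behaviour = as.list(tr$truth$behaviour),
         flocking_effects = as.list(scenario$flocking_effects),
         covariate_effects = as.list(scenario$covariate_effects),
         baseline_shift = scenario$baseline_shift),
    paths$truth, auto_unbox = TRUE, digits = NA)
  co_log("info", "pipeline", sprintf("wrote synthetic inputs for %d species to %s",
                                     scenario$n_species, dir))
  invisible(paths)
}

#' Run the full analysis pipeline on an input directory
#'
#' Executes the stage sequence COA -> cohort timing -> trait assembly ->
#' phylogenetic regression for every season present, fitting both model
#' variants per season: Model A (binary flocking over the full classified
#' pool) and Model B (three-level flocking behaviour over the subset with
#' resolved cohort timing). Writes per-stage CSV/JSON outputs and a run
#' manifest (input digests, seed, output paths) to `output_dir`.
#'
#' @param input_dir Directory holding `stratum_indices.csv`, `banding.csv`,
#'   `traits.csv`, `tree.nwk` (as written by [simulate_inputs()]).
#' @param output_dir Results directory (created if needed).
#' @param config A [coa_config()].
#' @param predictors Continuous predictor terms for the trait models.
#' @return Invisibly, a list with per-season results: `shift`, `coa`,
#'   `cohort`, and per-variant `trait_model` objects.
#' @export
run_pipeline <- function(input_dir, output_dir, config = coa_config(),
                         predictors = c("migration_distance_km",
                                        "generation_length_yr",
                                        "abs_population_trend",
                                        "total_range_km2")) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(input_dir, c("stratum_indices.csv", "banding.csv",
                                  "traits.csv", "tree.nwk"))
  names(paths) <- c("indices", "banding", "traits", "tree")
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("missing input file(s): ", paste(missing, collapse = ", ")))
  }
  idx <- read_stratum_indices(paths[["indices"]])
  band <- read_banding(paths[["banding"]])
  traits <- readr::read_csv(paths[["traits"]], show_col_types = FALSE)
  tree <- read_tree(paths[["tree"]])

  co_log("info", "pipeline", "stage 1/4: centres of abundance")
  seasons <- unique(idx$season)
  shifts <- species_shift(idx, config)
  readr::write_csv(shifts$coa, file.path(output_dir, "annual_coa.csv"))
  readr::write_csv(shifts$shift, file.path(output_dir, "coa_shift.csv"))

  co_log("info", "pipeline", "stage 2/4: cohort timing")
  cohort <- cohort_overlap(band, config)
  readr::write_csv(cohort, file.path(output_dir, "cohort_timing.csv"))

  co_log("info", "pipeline", "stage 3/4: trait assembly")
  co_log("info", "pipeline", "stage 4/4: phylogenetic regression")
  results <- purrr::map(seasons, function(se) {
    shift_se <- filter(shifts$shift, .data$season == se)
    tab <- assemble_traits(shift_se, cohort, traits)
    readr::write_csv(select(tab, -dplyr::any_of("displacement_m.trait")),
                     file.path(output_dir, paste0("analysis_table_", se, ".csv")))
    model_a <- fit_trait_models(
      filter(tab, .data$in_model_a), tree,
      predictors = c("flocking_binary", predictors), config = config)
    model_b <- fit_trait_models(
      filter(tab, .data$in_model_b), tree,
      predictors = c("flocking_behaviour", predictors), config = config)
    for (v in c("a", "b")) {
      m <- if (v == "a") model_a else model_b
      base <- file.path(output_dir, paste0("model_", v, "_", se))
      readr::write_csv(m$average$candidates, paste0(base, "_candidates.csv"))
      readr::write_csv(m$average$coefficients, paste0(base, "_coefficients.csv"))
      jsonlite::write_json(
        list(n = m$n, predictors = m$filtered_predictors,
             vif_removed = m$vif$removed,
             coefficients = m$average$coefficients,
             marginal_means = m$marginal_means),
        paste0(base, ".json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    list(season = se, table = tab, model_a = model_a, model_b = model_b)
  })
  names(results) <- seasons

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    inputs = as.list(tools::md5sum(paths)),
    outputs = list.files(output_dir),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(shift = shifts$shift, coa = shifts$coa, cohort = cohort,
                 models = results))
}
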