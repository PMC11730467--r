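#' Simulation scenario for the full pipeline
#'
#' Describes a synthetic study with known ground truth: a drifting bivariate
#' Gaussian abundance surface discretised to a regular stratum grid (standing
#' in for the survey-index posteriors), age-structured autumn banding
#' phenologies, Brownian trait evolution on a simulated phylogeny, and planted
#' additive flocking-class effects on the COA shift rate.
#'
#' Defaults describe the study system the pipeline targets: a 50-year window
#' (1970-2019), a continental-scale grid, posterior uncertainty of roughly 10%
#' CV on the abundance indices, an autumn passage centred on late September
#' with a passage spread of about 5 days, and flocking-class shift-rate
#' increments of about 2661 m/yr (mixed-age flocks) and 798 m/yr
#' (age-separated flocks) over solo migrants, with night migration slowing
#' shifts by about 1276 m/yr and migration distance adding about 723 m/yr per
#' standard deviation — the effect magnitudes characteristic of North American
#' landbird COA analyses.
#'
#' @param n_species Number of species (default 81).
#' @param n_strata Number of grid strata; must be a perfect square
#'   (default 144, a 12 x 12 grid).
#' @param lon_bounds,lat_bounds Grid extent in decimal degrees.
#' @param year_start,year_end Simulated survey window.
#' @param true_velocity Named numeric `c(east = , north = )` COA drift in
#'   metres/year.
#' @param surface_sd_deg Standard deviation of the Gaussian abundance surface
#'   (degrees).
#' @param population_trend Total-abundance trend, percent per year.
#' @param index_noise_sdlog Log-scale SD of multiplicative lognormal noise on
#'   stratum indices.
#' @param ci_cv Posterior CI width factor: `lo95/hi95 = median * exp(-+1.96 *
#'   ci_cv)`. Matched to `index_noise_sdlog` by default so the stated
#'   uncertainty equals the generating uncertainty.
#' @param adult_mean_day Mean autumn passage day of after-hatch-year birds.
#' @param cohort_separation Days by which the hatch-year passage lags the
#'   adult passage (0 = fully mixed-age timing).
#' @param passage_spread SD (days) of the passage sigmoid / individual timing.
#' @param breeding_lat,nonbreeding_lat Latitudes the banding sigmoid moves
#'   between.
#' @param banding_n Banding records per species.
#' @param banding_lat_noise SD (degrees) of latitude noise on banding records.
#' @param baseline_shift Solo-migrant baseline COA shift rate (m/yr).
#' @param flocking_effects Named numeric shift-rate increments (m/yr) for
#'   `solo`, `age_separated`, `mixed_age`.
#' @param covariate_effects Named numeric effects (m/yr per SD or per level)
#'   for `migration_distance_km` and `migratory_timing_night`.
#' @param brownian_sigma SD (m/yr) of the Brownian residual in shift rate
#'   accumulated over the unit-depth tree.
#' @param shift_se_meanlog,shift_se_sdlog Lognormal parameters of the
#'   per-species shift-rate measurement SE (m/yr).
#' @param flocking_rate Transition rate of the 3-state Markov process that
#'   evolves flocking class along the tree (higher = less phylogenetically
#'   clumped).
#' @param seed Integer master seed; all generators are deterministic given the
#'   scenario and this seed.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_species = 81L,
                         n_strata = 144L,
                         lon_bounds = c(-120, -80),
                         lat_bounds = c(20, 60),
                         year_start = 1970L,
                         year_end = 2019L,
                         true_velocity = c(east = 0, north = 2000),
                         surface_sd_deg = 3,
                         population_trend = 0.5,
                         index_noise_sdlog = 0.1,
                         ci_cv = index_noise_sdlog,
                         adult_mean_day = 260L,
                         cohort_separation = 0,
                         passage_spread = 5,
                         breeding_lat = 45,
                         nonbreeding_lat = 30,
                         banding_n = 3000L,
                         banding_lat_noise = 1.5,
                         baseline_shift = 2000,
                         flocking_effects = c(solo = 0, age_separated = 797.5,
                                              mixed_age = 2660.87),
                         covariate_effects = c(migration_distance_km = 723.43,
                                               migratory_timing_night = -1276.23),
                         brownian_sigma = 1500,
                         shift_se_meanlog = log(600),
                         shift_se_sdlog = 0.5,
                         flocking_rate = 3,
                         seed = 1L,
                         n_years = NULL) {
  if (!is.null(n_years)) year_end <- year_start + as.integer(n_years) - 1L
  side <- sqrt(n_strata)
  stopifnot(
    n_species >= 1, side == round(side),
    length(lon_bounds) == 2, length(lat_bounds) == 2,
    lon_bounds[1] < lon_bounds[2], lat_bounds[1] < lat_bounds[2],
    year_start < year_end, surface_sd_deg > 0,
    index_noise_sdlog >= 0, ci_cv >= 0, passage_spread > 0,
    banding_lat_noise >= 0, brownian_sigma >= 0, flocking_rate > 0,
    all(c("solo", "age_separated", "mixed_age") %in% names(flocking_effects))
  )
  structure(list(
    n_species = as.integer(n_species), n_strata = as.integer(n_strata),
    lon_bounds = lon_bounds, lat_bounds = lat_bounds,
    year_start = as.integer(year_start), year_end = as.integer(year_end),
    true_velocity = true_velocity, surface_sd_deg = surface_sd_deg,
    population_trend = population_trend,
    index_noise_sdlog = index_noise_sdlog, ci_cv = ci_cv,
    adult_mean_day = as.integer(adult_mean_day),
    cohort_separation = cohort_separation, passage_spread = passage_spread,
    breeding_lat = breeding_lat, nonbreeding_lat = nonbreeding_lat,
    banding_n = as.integer(banding_n), banding_lat_noise = banding_lat_noise,
    baseline_shift = baseline_shift, flocking_effects = flocking_effects,
    covariate_effects = covariate_effects, brownian_sigma = brownian_sigma,
    shift_se_meanlog = shift_se_meanlog, shift_se_sdlog = shift_se_sdlog,
    flocking_rate = flocking_rate, seed = as.integer(seed)
  ), class = "sim_scenario")
}

# Deterministic per-task sub-seed below 2^31, derived from the master seed and
# a task label so independent generators do not share streams.
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Simulate an ultrametric pure-birth phylogeny
#'
#' Yule (pure-birth) tree on `n_species` tips, rescaled so the root-to-tip
#' depth is 1. Tip labels are `sp001`, `sp002`, ...
#'
#' @param n_species Number of tips (at least 3).
#' @param seed Integer seed.
#' @return An \pkg{ape} `phylo` object.
#' @export
simulate_tree <- function(n_species, seed = 1L) {
  if (n_species < 3) abort("n_species must be at least 3")
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

#' Simulate stratum-level abundance index posteriors
#'
#' Discretises a bivariate Gaussian abundance surface to a regular lon/lat
#' stratum grid. The surface centre moves at the planted drift velocity
#' (converted to degrees at the scenario's starting latitude with 111320
#' m/degree and a cosine-corrected longitude), its total mass follows the
#' population trend, and each stratum-year index receives independent
#' multiplicative lognormal noise. 95th-percentile bounds are
#' `median * exp(-+1.96 * ci_cv)`, so the standard deviation recovered by
#' [sd_from_percentiles()] matches the generating noise scale when
#' `ci_cv = index_noise_sdlog`.
#'
#' @param scenario A [sim_scenario()].
#' @param species Species label.
#' @param season `"breeding"` or `"nonbreeding"`.
#' @param velocity Optional per-species override of the scenario drift,
#'   `c(east = , north = )` in metres/year.
#' @param seed Optional seed override (defaults to a deterministic function of
#'   the scenario seed and species label).
#' @return A stratum-index tibble with `index_sd` populated.
#' @export
simulate_index_series <- function(scenario, species,
                                  season = c("breeding", "nonbreeding"),
                                  velocity = scenario$true_velocity,
                                  seed = NULL) {
  season <- match.arg(season)
  stopifnot(inherits(scenario, "sim_scenario"))
  if (is.null(seed)) seed <- sub_seed(scenario$seed, paste0("idx:", species, season))
  set.seed(seed)

  years <- scenario$year_start:scenario$year_end
  t_rel <- years - scenario$year_start
  side <- as.integer(sqrt(scenario$n_strata))
  lon_c <- seq(scenario$lon_bounds[1], scenario$lon_bounds[2],
               length.out = side + 1)
  lat_c <- seq(scenario$lat_bounds[1], scenario$lat_bounds[2],
               length.out = side + 1)
  cell_lon <- (head(lon_c, -1) + tail(lon_c, -1)) / 2
  cell_lat <- (head(lat_c, -1) + tail(lat_c, -1)) / 2
  grid <- tidyr::expand_grid(centroid_lon = cell_lon, centroid_lat = cell_lat)
  grid$stratum_id <- sprintf("s%03d", seq_len(nrow(grid)))

  lon0 <- mean(scenario$lon_bounds)
  lat0 <- mean(scenario$lat_bounds)
  v_lat_deg <- velocity[["north"]] / 111320
  v_lon_deg <- velocity[["east"]] / (111320 * cos(lat0 * pi / 180))
  centre_lon <- lon0 + v_lon_deg * t_rel
  centre_lat <- lat0 + v_lat_deg * t_rel
  margin <- 2 * scenario$surface_sd_deg
  if (any(centre_lon < scenario$lon_bounds[1] + margin) ||
      any(centre_lon > scenario$lon_bounds[2] - margin) ||
      any(centre_lat < scenario$lat_bounds[1] + margin) ||
      any(centre_lat > scenario$lat_bounds[2] - margin)) {
    abort("planted drift carries the abundance surface too close to the grid edge within the year window")
  }

  out <- purrr::map2(years, seq_along(years), function(yr, i) {
    dens <- exp(-((grid$centroid_lon - centre_lon[i])^2 +
                    (grid$centroid_lat - centre_lat[i])^2) /
                  (2 * scenario$surface_sd_deg^2))
    mass <- (1 + scenario$population_trend / 100)^(t_rel[i])
    noise <- if (scenario$index_noise_sdlog > 0) {
      rlnorm(nrow(grid), 0, scenario$index_noise_sdlog)
    } else rep(1, nrow(grid))
    med <- dens * mass * noise
    tibble(
      species = species, season = season, stratum_id = grid$stratum_id,
      centroid_lon = grid$centroid_lon, centroid_lat = grid$centroid_lat,
      year = yr, index_median = med,
      index_lo95 = med * exp(-1.96 * scenario$ci_cv),
      index_hi95 = med * exp(1.96 * scenario$ci_cv)
    )
  }) %>% bind_rows()
  mutate(out, index_sd = sd_from_percentiles(.data$index_lo95, .data$index_hi95))
}

#' Simulate banding-event records with age-structured autumn phenology
#'
#' For each age class, individual passage timing is normal around the class
#' mean day (`adult_mean_day` for AHY; plus `cohort_separation` for HY).
#' Banding days are drawn with three times the passage spread so the fitted
#' latitude-by-day curves have support on the shoulders of the migration; the
#' expected banding latitude declines sigmoidally from `breeding_lat` to
#' `nonbreeding_lat` as passage progresses, plus normal noise.
#'
#' @inheritParams simulate_index_series
#' @param n_records Total records (split evenly between HY and AHY).
#' @return A banding-record tibble (`species`, `julian_day`, `latitude`,
#'   `age_class`).
#' @export
simulate_banding <- function(scenario, species,
                             n_records = scenario$banding_n, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (scenario$passage_spread <= 0) abort("passage_spread must be positive")
  if (n_records < 1) abort("n_records must be positive: empty output requested")
  if (is.null(seed)) seed <- sub_seed(scenario$seed, paste0("band:", species))
  set.seed(seed)

  means <- c(AHY = scenario$adult_mean_day,
             HY = scenario$adult_mean_day + scenario$cohort_separation)
  n_class <- c(AHY = ceiling(n_records / 2), HY = floor(n_records / 2))
  out <- purrr::map(c("AHY", "HY"), function(cl) {
    n <- n_class[[cl]]
    if (n == 0) return(NULL)
    day <- round(rnorm(n, means[[cl]], 3 * scenario$passage_spread))
    day <- pmin(pmax(day, 1L), 366L)
    progress <- plogis((day - means[[cl]]) / scenario$passage_spread)
    lat <- scenario$breeding_lat -
      (scenario$breeding_lat - scenario$nonbreeding_lat) * progress +
      rnorm(n, 0, scenario$banding_lat_noise)
    tibble(species = species, julian_day = as.integer(day),
           latitude = lat, age_class = cl)
  }) %>% bind_rows()
  arrange(out, .data$julian_day)
}

#' Simulate species traits with planted flocking effects on shift rate
#'
#' Continuous covariates evolve as Brownian motion on the tree; flocking
#' behaviour evolves as a 3-state equal-rates Markov process along the
#' branches (phylogenetically clumped, all three classes guaranteed present);
#' migratory timing (day/night) evolves as a 2-state Markov process. The true
#' COA shift rate is
#' `baseline + flocking effect + covariate effects + Brownian residual`,
#' and the observed shift adds normal measurement error with a per-species SE
#' drawn from a lognormal distribution — exactly the generative model the
#' measurement-error phylogenetic regression assumes.
#'
#' @param tree A `phylo` whose tips are the species set.
#' @param scenario A [sim_scenario()].
#' @param seed Optional seed override.
#' @return A list: `traits` (tibble with species, flocking/behaviour/timing
#'   factors, continuous covariates, observed `displacement_m` and
#'   `displacement_se_m`) and `truth` (the planted effects and per-species
#'   true shifts).
#' @export
simulate_traits <- function(tree, scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"), inherits(tree, "phylo"))
  if (is.null(seed)) seed <- sub_seed(scenario$seed, "traits")
  set.seed(seed)
  n <- length(tree$tip.label)

  bm <- function() as.numeric(ape::rTraitCont(tree, model = "BM", sigma = 1))
  dist_z <- bm()
  gen_z <- bm()
  habitat_z <- bm()
  diet_z <- bm()
  trend_z <- bm()
  range_z <- bm()

  states <- c("solo", "age_separated", "mixed_age")
  beh <- sim_markov_states(tree, states, scenario$flocking_rate)
  for (i in seq_len(50)) {
    if (length(unique(beh)) == 3) break
    beh <- sim_markov_states(tree, states, scenario$flocking_rate)
  }
  if (length(unique(beh)) < 3) {
    abort("could not realise all three flocking classes on this tree; raise flocking_rate")
  }
  timing <- sim_markov_states(tree, c("day", "night"), scenario$flocking_rate)

  resid <- as.numeric(ape::rTraitCont(tree, model = "BM",
                                      sigma = scenario$brownian_sigma))
  true_shift <- scenario$baseline_shift +
    scenario$flocking_effects[beh] +
    scenario$covariate_effects[["migration_distance_km"]] * dist_z +
    scenario$covariate_effects[["migratory_timing_night"]] * (timing == "night") +
    resid
  se <- rlnorm(n, scenario$shift_se_meanlog, scenario$shift_se_sdlog)
  obs_shift <- true_shift + rnorm(n, 0, se)

  traits <- tibble(
    species = tree$tip.label,
    flocking_behaviour = factor(beh, levels = states),
    flocking_binary = factor(ifelse(beh == "solo", "solo", "flocking"),
                             levels = c("solo", "flocking")),
    migratory_timing = factor(timing, levels = c("day", "night")),
    migration_distance_km = 2000 + 800 * dist_z,
    generation_length_yr = pmax(1, 4 + gen_z),
    habitat_specialism = pmin(100, pmax(0, 50 + 15 * habitat_z)),
    diet_specialism = pmin(100, pmax(0, 50 + 15 * diet_z)),
    population_trend = 1.5 * trend_z,
    total_range_km2 = exp(14 + 0.5 * range_z),
    sampled_range_km2 = exp(14 + 0.5 * range_z) * runif(n, 0.3, 1),
    displacement_m = as.numeric(obs_shift),
    displacement_se_m = se
  )
  list(
    traits = traits,
    truth = list(
      baseline_shift = scenario$baseline_shift,
      flocking_effects = scenario$flocking_effects,
      covariate_effects = scenario$covariate_effects,
      true_shift = setNames(as.numeric(true_shift), tree$tip.label),
      behaviour = setNames(beh, tree$tip.label)
    )
  )
}

# Equal-rates k-state Markov walk along tree branches, root state uniform.
# Uses the current RNG stream (callers seed it).
sim_markov_states <- function(tree, states, rate) {
  k <- length(states)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  state <- integer(n_node)
  root <- n_tip + 1L
  state[root] <- sample.int(k, 1)
  # preorder over edges
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    len <- ord$edge.length[e]
    # ER process: switch to a uniformly chosen different state with
    # probability (k-1)/k * (1 - exp(-k * rate * len / (k-1)))
    p_switch <- (k - 1) / k * (1 - exp(-k * rate * len / (k - 1)))
    if (runif(1) < p_switch) {
      others <- setdiff(seq_len(k), state[par])
      state[child] <- others[sample.int(length(others), 1)]
    } else {
      state[child] <- state[par]
    }
  }
  states[state[seq_len(n_tip)]]
}
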