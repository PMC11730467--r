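test_that("simulated trees are ultrametric unit-depth Yule trees", {
  tr <- simulate_tree(3, seed = 1)
  expect_equal(length(tr$tip.label), 3)
  depths <- ape::node.depth.edgelength(tr)[seq_len(3)]
  expect_equal(depths, rep(1, 3), tolerance = 1e-10)

  a <- ape::write.tree(simulate_tree(20, seed = 5))
  b <- ape::write.tree(simulate_tree(20, seed = 5))
  expect_identical(a, b)
  expect_false(identical(a, ape::write.tree(simulate_tree(20, seed = 6))))
  expect_error(simulate_tree(2), "at least 3")
})

test_that("tree imbalance is consistent with the Yule model", {
  # independent null: under the equal-rates Markov (Yule) model the root
  # split of an n-tip tree is uniform on 1..n-1, recursively, so the Colless
  # index can be sampled without building trees at all
  colless_null <- function(n) {
    if (n <= 2) return(0)
    m <- sample.int(n - 1, 1)
    abs(n - 2 * m) + Recall(m) + Recall(n - m)
  }
  set.seed(99)
  null_draws <- replicate(500, colless_null(100))
  band <- quantile(null_draws, c(0.005, 0.995))
  tr <- simulate_tree(100, seed = 42)
  bal <- ape::balance(tr)
  obs <- sum(abs(bal[, 1] - bal[, 2]))
  expect_gte(obs, band[[1]])
  expect_lte(obs, band[[2]])
})

test_that("index surfaces honour planted drift, scale invariance and bounds", {
  still <- sim_scenario(true_velocity = c(east = 0, north = 0),
                        index_noise_sdlog = 0, n_strata = 36,
                        year_start = 2000, year_end = 2009, seed = 2)
  idx <- simulate_index_series(still, "spA")
  coa <- annual_coa(idx)
  expect_lt(max(coa$coa_lat) - min(coa$coa_lat), 1e-9)
  expect_lt(max(coa$coa_lon) - min(coa$coa_lon), 1e-9)

  # the weighted COA is scale invariant: doubling all indices changes nothing
  doubled <- dplyr::mutate(idx, index_median = index_median * 2,
                           index_lo95 = index_lo95 * 2,
                           index_hi95 = index_hi95 * 2,
                           index_sd = index_sd * 2)
  coa2 <- annual_coa(doubled)
  expect_equal(coa2$coa_lat, coa$coa_lat, tolerance = 1e-12)
  expect_equal(coa2$coa_lon, coa$coa_lon, tolerance = 1e-12)

  runaway <- sim_scenario(true_velocity = c(east = 0, north = 60000), seed = 2)
  expect_error(simulate_index_series(runaway, "spA"), "grid edge")

  a <- simulate_index_series(still, "spA")
  b <- simulate_index_series(still, "spA")
  expect_identical(a, b)
})

test_that("noiseless planted drift is recovered within 1%", {
  scn <- sim_scenario(true_velocity = c(east = 0, north = 5000),
                      index_noise_sdlog = 0, seed = 4)
  sh <- species_shift(simulate_index_series(scn, "spA"))$shift
  expect_lt(abs(sh$displacement_m - 5000) / 5000, 0.01)
  expect_lt(abs(sh$trend_lon), 1e-6)
})

test_that("banding generator separates cohorts and validates inputs", {
  scn <- sim_scenario(cohort_separation = 40, seed = 8)
  b <- simulate_banding(scn, "spA")
  expect_equal(nrow(b), scn$banding_n)
  hy_mean <- mean(b$julian_day[b$age_class == "HY"])
  ahy_mean <- mean(b$julian_day[b$age_class == "AHY"])
  expect_gt(hy_mean - ahy_mean, 30)
  expect_error(simulate_banding(scn, "spA", n_records = 0), "empty")
  expect_error(sim_scenario(passage_spread = 0), "passage_spread")
  expect_identical(simulate_banding(scn, "spA"), simulate_banding(scn, "spA"))
})

test_that("trait generator plants exact effects when the Brownian residual is off", {
  scn <- sim_scenario(n_species = 30, brownian_sigma = 0, seed = 21)
  tree <- simulate_tree(30, seed = 21)
  tr <- simulate_traits(tree, scn)
  expect_setequal(unique(as.character(tr$traits$flocking_behaviour)),
                  c("solo", "age_separated", "mixed_age"))
  dist_z <- (tr$traits$migration_distance_km - 2000) / 800
  reconstructed <- scn$baseline_shift +
    scn$flocking_effects[as.character(tr$traits$flocking_behaviour)] +
    scn$covariate_effects[["migration_distance_km"]] * dist_z +
    scn$covariate_effects[["migratory_timing_night"]] *
      (tr$traits$migratory_timing == "night")
  expect_equal(unname(tr$truth$true_shift), unname(reconstructed),
               tolerance = 1e-9)
  expect_true(all(tr$traits$displacement_se_m > 0))
  expect_true(all(tr$traits$sampled_range_km2 <= tr$traits$total_range_km2))
})
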