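test_that("flocking classification follows the strict size threshold", {
  expect_equal(classify_flocking(3, 2), "flocking")
  expect_equal(classify_flocking(2, 2), "solo")
  expect_equal(unname(vapply(c(2, 5, 10), function(th) classify_flocking(7, th),
                             character(1))),
               c("flocking", "flocking", "solo"))
  expect_error(classify_flocking(0), "positive")
  # monotone in the threshold: raising it never converts solo -> flocking
  set.seed(1)
  sizes <- sample(1:60, 30, replace = TRUE)
  f2 <- classify_flocking(sizes, 2)
  f5 <- classify_flocking(sizes, 5)
  f10 <- classify_flocking(sizes, 10)
  expect_false(any(f2 == "solo" & f5 == "flocking"))
  expect_false(any(f5 == "solo" & f10 == "flocking"))
})

test_that("flock size categories split at 2 and 10", {
  expect_equal(flock_size_category(c(1, 2, 3, 5, 9, 10, 50)),
               c("solo", "solo", "small", "small", "small", "large", "large"))
})

test_that("combined flocking behaviour applies the solo dominance rule", {
  expect_equal(combine_flocking_behaviour("flocking", "mixed_age"),
               "mixed_age_flocks")
  expect_equal(combine_flocking_behaviour("flocking", "age_separated"),
               "age_separated_flocks")
  expect_equal(combine_flocking_behaviour("solo", "mixed_age"), "solo")
  expect_equal(combine_flocking_behaviour("flocking", "insufficient_data"),
               "insufficient_data")
})

test_that("great-circle distance matches analytic values and metric axioms", {
  expect_equal(migration_distance(0, 0, 0, 0), 0)
  expect_equal(migration_distance(0, 0, 180, 0), pi * 6371.0088,
               tolerance = 1e-6)
  expect_equal(migration_distance(0, 0, 0, 90), pi * 6371.0088 / 2,
               tolerance = 1e-6)
  set.seed(2)
  for (r in 1:20) {
    p <- matrix(c(runif(3, -180, 180), runif(3, -90, 90)), ncol = 2)
    d_ab <- migration_distance(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    d_ba <- migration_distance(p[2, 1], p[2, 2], p[1, 1], p[1, 2])
    d_ac <- migration_distance(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    d_cb <- migration_distance(p[3, 1], p[3, 2], p[2, 1], p[2, 2])
    expect_equal(d_ab, d_ba, tolerance = 1e-10)
    expect_lte(d_ab, d_ac + d_cb + 1e-9)
  }
  expect_error(migration_distance(0, 95, 0, 0), "bounds")
})

test_that("absolute trend and Z-scoring round-trip exactly", {
  expect_equal(absolute_trend(c(-2.3, 0, 1.7)), c(2.3, 0, 1.7))

  df <- tibble::tibble(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- zscore_columns(df, c("a", "b"))
  expect_equal(z$a, c(-1, 0, 1)) # sample-SD convention: sd(1:3) = 1
  expect_equal(mean(z$b), 0, tolerance = 1e-12)
  expect_equal(sd(z$b), 1, tolerance = 1e-12)

  # planted coefficient back-transforms through the recorded scaling
  set.seed(3)
  x <- rnorm(40, 5, 3)
  beta <- 2.5
  y <- 1 + beta * x
  d2 <- zscore_columns(tibble::tibble(x = x), "x")
  sc <- attr(d2, "scaling")
  b_z <- coef(lm(y ~ d2$x))[2]
  expect_equal(unname(b_z / sc$sd), beta, tolerance = 1e-9)

  expect_error(zscore_columns(tibble::tibble(k = rep(1, 5)), "k"), "k")
})

test_that("assembly nests the model pools and propagates insufficient data", {
  scn <- sim_scenario(n_species = 25, seed = 13)
  tree <- simulate_tree(25, seed = 13)
  tr <- simulate_traits(tree, scn)
  traits <- tr$traits
  traits$flocking_behaviour <- NULL
  # cohort table: resolve timing for some flocking species only
  cohort <- tibble::tibble(
    species = traits$species,
    classification = rep(c("mixed_age", "age_separated", "insufficient_data"),
                         length.out = 25)
  )
  shift <- tibble::tibble(species = traits$species,
                          displacement_m = traits$displacement_m,
                          displacement_se_m = traits$displacement_se_m,
                          weight = 1 / traits$displacement_se_m)
  traits <- dplyr::select(traits, -"displacement_m", -"displacement_se_m")
  tab <- assemble_traits(shift, cohort, traits,
                         predictors = c("migration_distance_km",
                                        "generation_length_yr"))
  expect_true(all(tab$species[tab$in_model_b] %in% tab$species[tab$in_model_a]))
  expect_true(all(tab$flocking_behaviour[tab$in_model_b] != "insufficient_data"))
  # solo dominance holds regardless of cohort label
  solo <- tab$flocking_binary == "solo"
  expect_true(all(tab$flocking_behaviour[solo] == "solo"))
  # scaling metadata present for back-transformation
  expect_s3_class(attr(tab, "scaling"), "tbl_df")
  expect_equal(mean(tab$migration_distance_km), 0, tolerance = 1e-9)
})
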