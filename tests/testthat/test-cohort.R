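make_linear_records <- function(n_per_class = 800, slope = -0.1,
                                intercept = 60, days = 180:300) {
  day <- rep(days, length.out = n_per_class)
  tibble::tibble(
    species = "lin",
    julian_day = rep(as.integer(day), 2),
    latitude = rep(intercept + slope * day, 2),
    age_class = rep(c("HY", "AHY"), each = n_per_class)
  )
}

test_that("the age smoother reproduces a noiseless linear signal", {
  rec <- make_linear_records()
  fit <- fit_age_smoother(rec, min_total = 1000, min_per_class = 30)
  expect_equal(fit$status, "ok")
  truth <- 60 - 0.1 * fit$curves$julian_day
  expect_lt(max(abs(fit$curves$fitted - truth)), 0.01)
  # identical record sets fed as the two classes give identical curves
  wide <- tidyr::pivot_wider(fit$curves, names_from = "age_class",
                             values_from = "fitted")
  expect_equal(wide$HY, wide$AHY, tolerance = 1e-8)
})

test_that("record-count floors yield an insufficient_data status, not an error", {
  rec <- make_linear_records(n_per_class = 100)
  fit <- fit_age_smoother(rec, min_total = 1000, min_per_class = 30)
  expect_equal(fit$status, "insufficient_data")
  expect_null(fit$curves)
})

test_that("autumn window detection finds the declining interval", {
  # monotone decline from day 180 to 300
  day <- 150:330
  value <- ifelse(day < 180, 45,
                  ifelse(day > 300, 30, 45 - 15 * (day - 180) / 120))
  w <- window_from_curve(day, value)
  expect_equal(w$status, "ok")
  expect_lt(abs(w$window[1] - 180), 5 + 1e-9)
  expect_lt(abs(w$window[2] - 300), 5 + 1e-9)

  flat <- window_from_curve(day, rep(40, length(day)))
  expect_equal(flat$status, "insufficient_data")

  # spring increase then autumn decrease: the declining limb is selected
  spring_autumn <- ifelse(day < 240, 30 + 15 * (day - 150) / 90,
                          45 - 15 * (day - 240) / 90)
  w2 <- window_from_curve(day, spring_autumn)
  expect_equal(w2$status, "ok")
  expect_gt(w2$window[1], 235)
  expect_gt(w2$window[2], w2$window[1])
})

test_that("overlap index matches an independent fine-grid integrator", {
  day <- 180:300
  f_a <- plogis(-(day - 240) / 8)
  f_b <- plogis(-(day - 260) / 12)
  got <- overlap_index(day, f_a, f_b)

  # independent oracle: trapezoid rule on linear interpolants at 1e-3 days
  norm01 <- function(v) (v - min(v)) / (max(v) - min(v))
  fine <- seq(180, 300, by = 1e-3)
  a_f <- approx(day, norm01(f_a), xout = fine)$y
  b_f <- approx(day, norm01(f_b), xout = fine)$y
  trapz <- function(x, y) sum((head(y, -1) + tail(y, -1)) / 2 * diff(x))
  oracle <- trapz(fine, pmin(a_f, b_f)) / trapz(fine, pmax(a_f, b_f))
  expect_lt(abs(got - oracle), 1e-6)
})

test_that("overlap index honours identity, disjointness, symmetry and affine invariance", {
  day <- 1:200
  f <- dnorm(day, 80, 15)
  expect_equal(overlap_index(day, f, f), 1, tolerance = 1e-12)

  # disjoint support after normalisation
  tri_a <- pmax(0, 1 - abs(day - 50) / 20)
  tri_b <- pmax(0, 1 - abs(day - 150) / 20)
  expect_equal(overlap_index(day, tri_a, tri_b), 0)

  g <- dnorm(day, 120, 25)
  expect_equal(overlap_index(day, f, g), overlap_index(day, g, f),
               tolerance = 1e-12)
  # min-max normalisation absorbs affine transforms of either raw curve
  expect_equal(overlap_index(day, 3 * f + 7, g),
               overlap_index(day, f, g), tolerance = 1e-12)

  expect_error(overlap_index(day, rep(1, 200), f), "degenerate")
})

test_that("threshold classification uses a strict inequality at 0.85", {
  expect_equal(classify_cohort_timing(0.90), "mixed_age")
  expect_equal(classify_cohort_timing(0.85), "age_separated")
  expect_equal(classify_cohort_timing(0.10), "age_separated")
})

test_that("mean overlap decreases with planted cohort separation", {
  seps <- c(0, 10, 20, 30, 40)
  seeds <- 11:13
  mean_ov <- vapply(seps, function(sp) {
    mean(vapply(seeds, function(sd) {
      scn <- sim_scenario(cohort_separation = sp, banding_n = 2000, seed = sd)
      cohort_overlap(simulate_banding(scn, "sp"))$overlap_index
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ov) <= 0.02))
  expect_gt(mean_ov[1], 0.85)
  expect_lt(mean_ov[5], 0.6)
})

test_that("cohort_overlap flags species below the record floor", {
  scn <- sim_scenario(banding_n = 500, seed = 9)
  res <- cohort_overlap(simulate_banding(scn, "rare"))
  expect_equal(res$classification, "insufficient_data")
})
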