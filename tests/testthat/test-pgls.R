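test_that("Brownian correlation matches a brute-force MRCA traversal", {
  expect_equal(unname(brownian_correlation(star_tree(5))), diag(5))

  sisters <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,C:1);")
  C <- brownian_correlation(sisters)
  expect_equal(C["A", "B"], 0.5)
  expect_equal(C["A", "C"], 0)

  tr <- simulate_tree(20, seed = 31)
  C2 <- brownian_correlation(tr)
  # independent oracle: shared root-to-MRCA path length by explicit
  # ancestor-path intersection
  n <- 20
  root <- n + 1L
  parent <- integer(max(tr$edge))
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  depth <- ape::node.depth.edgelength(tr)
  anc_path <- function(i) {
    path <- i
    while (i != root) {
      i <- parent[i]
      path <- c(path, i)
    }
    path
  }
  for (i in 1:5) for (j in 1:20) {
    shared <- intersect(anc_path(i), anc_path(j))
    expected <- if (i == j) 1 else max(depth[setdiff(shared, c(i, j))])
    expect_equal(unname(C2[tr$tip.label[i], tr$tip.label[j]]), expected,
                 tolerance = 1e-10)
  }
})

test_that("PGLS collapses to OLS and weighted OLS in the degenerate limits", {
  set.seed(41)
  n <- 30
  x <- rnorm(n)
  y <- 1 + 2 * x + rnorm(n)
  X <- cbind("(Intercept)" = 1, x = x)
  C <- diag(n)

  ols <- coef(lm(y ~ x))
  f <- pgls_fit(y, X, C, rep(0, n))
  expect_equal(unname(f$coefficients), unname(ols), tolerance = 1e-8)
  f2 <- pgls_fit(y, X, C, rep(0.7, n)) # constant SE: still OLS coefficients
  expect_equal(unname(f2$coefficients), unname(ols), tolerance = 1e-8)

  # weights-only model equals the weighted-OLS closed form
  se <- runif(n, 0.3, 2)
  W <- diag(1 / se^2)
  beta_wls <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  f3 <- pgls_fit(y, X, C, se, error_model = "weights_only")
  expect_equal(unname(f3$coefficients), as.numeric(beta_wls), tolerance = 1e-8)
})

test_that("an observation with enormous SE loses its leverage", {
  set.seed(43)
  n <- 25
  tr <- simulate_tree(n, seed = 43)
  C <- brownian_correlation(tr)
  x <- as.numeric(ape::rTraitCont(tr, sigma = 1))
  y <- 1 + x + as.numeric(ape::rTraitCont(tr, sigma = 1))
  se <- rep(0.2, n)
  se[1] <- 1e6
  X <- cbind(1, x = x)
  f_all <- pgls_fit(y, X, C, se)
  f_drop <- pgls_fit(y[-1], X[-1, ], C[-1, -1], se[-1])
  expect_lt(max(abs(f_all$coefficients - f_drop$coefficients)), 1e-3)
})

test_that("coefficients agree with the phytools measurement-error routine", {
  skip_if_not_installed("phytools")
  set.seed(47)
  n <- 40
  tr <- simulate_tree(n, seed = 47)
  C <- brownian_correlation(tr)
  x <- as.numeric(ape::rTraitCont(tr, sigma = 1))
  se <- rlnorm(n, log(0.5), 0.3)
  y <- 2 + 1.5 * x + as.numeric(ape::rTraitCont(tr, sigma = 1)) +
    rnorm(n, 0, se)
  f <- pgls_fit(y, cbind(1, x = x), C, se)
  d <- data.frame(y = y, x = x, row.names = tr$tip.label)
  o <- suppressWarnings(phytools::pgls.SEy(
    y ~ x, data = d, tree = tr, se = setNames(se, tr$tip.label),
    method = "REML"))
  # pgls.SEy folds the SEs into fixed variance weights rather than the exact
  # additive form, so agreement is close but not exact
  expect_equal(unname(f$coefficients), unname(coef(o)), tolerance = 0.05)
})

test_that("AICc honours its closed form and the reported likelihood", {
  set.seed(53)
  n <- 40
  tr <- simulate_tree(n, seed = 53)
  C <- brownian_correlation(tr)
  x <- as.numeric(ape::rTraitCont(tr, sigma = 1))
  y <- x + as.numeric(ape::rTraitCont(tr, sigma = 1)) + rnorm(n, 0, 0.3)
  f <- pgls_fit(y, cbind(1, x = x), C, rep(0.3, n))
  expect_equal(f$AICc,
               -2 * f$logLik + 2 * f$k + 2 * f$k * (f$k + 1) / (f$n - f$k - 1),
               tolerance = 1e-12)
  expect_gt(f$sigma2, 0)
})

test_that("VIF values and stepwise filtering match brute-force regression", {
  set.seed(59)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  X_orth <- qr.Q(qr(X))
  colnames(X_orth) <- c("a", "b", "c")
  # columns are orthogonal but not exactly mean-centred, so VIFs sit at
  # 1 + O(1/n)
  expect_equal(unname(vif_values(X_orth)), rep(1, 3), tolerance = 1e-3)

  # correlated trio against 1/(1 - R^2) from explicit lm fits
  z <- rnorm(n)
  Xc <- cbind(a = z + rnorm(n, 0, 0.45), b = z + rnorm(n, 0, 0.45),
              c = z + rnorm(n, 0, 0.45))
  v <- vif_values(Xc)
  for (j in 1:3) {
    r2 <- summary(lm(Xc[, j] ~ Xc[, -j]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-8)
  }

  # duplicated predictor: the later copy's term is removed
  d <- tibble::tibble(a = rnorm(n), b = rnorm(n))
  d$a_copy <- d$a
  out <- vif_filter(d, c("a", "b", "a_copy"), cutoff = 5)
  expect_equal(out$removed, "a_copy")
  expect_setequal(out$terms, c("a", "b"))

  # orthogonal design: nothing removed
  d2 <- tibble::tibble(a = X_orth[, 1], b = X_orth[, 2])
  out2 <- vif_filter(d2, c("a", "b"), cutoff = 5)
  expect_equal(out2$removed, character(0))
})

test_that("candidate enumeration respects blocks and the samples-per-variable floor", {
  set.seed(61)
  d <- tibble::tibble(
    a = rnorm(120), b = rnorm(120), c = rnorm(120),
    f = factor(rep(c("solo", "small", "large"), 40))
  )
  cands <- candidate_models(c("a", "b", "c"), d, n = 120)
  expect_length(cands, 8) # 2^3 including intercept-only

  # n = 25: any 3-column candidate is excluded (25/3 < 10)
  cands2 <- candidate_models(c("a", "b", "c"), d[1:25, ], n = 25)
  sizes <- lengths(cands2)
  expect_true(all(sizes <= 2))
  expect_length(cands2, 7)

  # a 3-level factor contributes 2 dummy columns that travel together
  cands3 <- candidate_models(c("a", "f"), d, n = 120)
  expect_length(cands3, 4)
  has_f <- vapply(cands3, function(s) "f" %in% s, logical(1))
  expect_equal(sum(has_f), 2)
})

test_that("model averaging reproduces hand-computed Akaike weights", {
  f1 <- fake_fit(100.0, c("(Intercept)", "a"), c(1, 2.0), c(0.1, 0.3))
  f2 <- fake_fit(101.0, c("(Intercept)"), 1.2, 0.15)
  f3 <- fake_fit(103.0, c("(Intercept)", "b"), c(0.9, 5), c(0.1, 1))

  avg <- model_average(list(f1, f2, f3), window = 2)
  cand <- avg$candidates
  expect_equal(cand$retained, c(TRUE, TRUE, FALSE))
  w1 <- 1 / (1 + exp(-0.5))
  w2 <- exp(-0.5) / (1 + exp(-0.5))
  expect_equal(cand$weight[1:2], c(w1, w2), tolerance = 1e-12)
  expect_equal(sum(cand$weight), 1, tolerance = 1e-12)

  co <- avg$coefficients
  # full (zero-substituted) average of the slope present only in model 1
  a_row <- co[co$term == "a", ]
  expect_equal(a_row$estimate, w1 * 2.0, tolerance = 1e-12)
  expect_equal(a_row$std.error,
               w1 * sqrt(0.3^2 + (2 - w1 * 2)^2) + w2 * sqrt(0 + (0 - w1 * 2)^2),
               tolerance = 1e-12)

  # single retained model: averaged coefficients are that model's
  avg1 <- model_average(list(f1), window = 2)
  expect_equal(avg1$coefficients$estimate, unname(f1$coefficients))

  # equal-AICc pair: symmetric 0.5/0.5 weights
  avg2 <- model_average(list(f1, fake_fit(100.0, "(Intercept)", 1, 0.1)))
  expect_equal(avg2$candidates$weight, c(0.5, 0.5))

  # conditional averaging renormalises over models containing the term
  avg3 <- model_average(list(f1, f2), method = "conditional")
  expect_equal(avg3$coefficients$estimate[avg3$coefficients$term == "a"], 2.0)
})

test_that("a planted effect is recovered through the full trait-model surface", {
  set.seed(67)
  scn <- sim_scenario(n_species = 60, seed = 71)
  tree <- simulate_tree(60, seed = 71)
  tr <- simulate_traits(tree, scn)
  tab <- zscore_columns(tr$traits, c("migration_distance_km",
                                     "generation_length_yr"))
  m <- fit_trait_models(tab, tree,
                        predictors = c("flocking_behaviour",
                                       "migration_distance_km",
                                       "generation_length_yr"))
  expect_s3_class(m$global, "pgls_fit")
  expect_s3_class(m$average, "averaged_model")
  td <- tidy(m$global)
  est <- td$estimate[td$term == "flocking_behaviourmixed_age"]
  se <- td$std.error[td$term == "flocking_behaviourmixed_age"]
  expect_lt(abs(est - 2660.87), 3 * se)
  # reference level is solo: marginal means exist for all three classes
  expect_setequal(m$marginal_means$level,
                  c("solo", "age_separated", "mixed_age"))
  expect_gt(m$marginal_means$mean[m$marginal_means$level == "mixed_age"],
            m$marginal_means$mean[m$marginal_means$level == "solo"])
})
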