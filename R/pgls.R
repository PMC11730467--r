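#' Brownian-motion correlation matrix from a phylogeny
#'
#' Under Brownian trait evolution the covariance between two tips is the
#' shared root-to-MRCA path length. For an ultrametric tree (all tips at
#' depth \eqn{T}) dividing by \eqn{T} gives a correlation matrix with unit
#' diagonal; a non-ultrametric tree draws a warning and is scaled by the
#' per-tip depths, \eqn{C_{ij}/\sqrt{C_{ii} C_{jj}}}.
#'
#' @param tree A `phylo` with branch lengths.
#' @return A species-by-species correlation matrix (unit diagonal), rows and
#'   columns named by tip label.
#' @export
brownian_correlation <- function(tree) {
  V <- ape::vcv(tree)
  d <- diag(V)
  if (max(d) - min(d) > 1e-8 * max(d)) {
    warn("tree is not ultrametric; scaling covariance by per-tip depths")
    V <- V / sqrt(outer(d, d))
  } else {
    V <- V / max(d)
  }
  diag(V) <- 1
  V
}

# Profile log-likelihood machinery for V = sigma2 * C + diag(se^2)
# (or V = sigma2 * diag(se^2) for the weights-only sensitivity model).
# Returns the profiled ML log-likelihood and, for REML, the restricted
# log-likelihood (ML minus 0.5 log|X' V^-1 X|, constants dropped).
pgls_loglik <- function(sigma2, y, X, C, se2, error_model) {
  V <- switch(error_model,
    additive = sigma2 * C + diag(se2, nrow(C)),
    weights_only = sigma2 * diag(se2, length(y))
  )
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf, ll_reml = -Inf))
  logdet <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- tryCatch(solve(XtViX, crossprod(X, Vi_y)),
                   error = function(e) NULL)
  if (is.null(beta)) return(list(ll = -Inf, ll_reml = -Inf))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  quad <- as.numeric(crossprod(r, Vi_r))
  n <- length(y)
  ll <- -0.5 * (n * log(2 * pi) + logdet + quad)
  list(
    ll = ll,
    ll_reml = ll - 0.5 * as.numeric(determinant(XtViX)$modulus),
    beta = as.numeric(beta),
    vcov = solve(XtViX)
  )
}

#' Phylogenetic GLS with known response measurement error
#'
#' Generalized least squares with residual covariance
#' \deqn{V = \sigma^2 C + \mathrm{diag}(SE_y^2),}
#' where \eqn{C} is the Brownian correlation from the phylogeny and
#' \eqn{SE_y} the known per-species standard errors of the response (the
#' reciprocal-SE weighting of the shift estimates). The Brownian rate
#' \eqn{\sigma^2} is profiled by one-dimensional maximum likelihood;
#' coefficients are \eqn{(X^\top V^{-1} X)^{-1} X^\top V^{-1} y} with
#' covariance \eqn{(X^\top V^{-1} X)^{-1}}. With a star phylogeny and zero
#' SEs this reduces exactly to ordinary least squares. The alternative
#' `error_model = "weights_only"` drops the phylogenetic term and uses pure
#' reciprocal-variance weights (a sensitivity setting; requires all SEs
#' positive).
#'
#' @param y Numeric response vector.
#' @param X Design matrix (including the intercept column).
#' @param C Species correlation matrix aligned with `y`.
#' @param se_y Per-observation standard errors (>= 0).
#' @param error_model `"additive"` (default) or `"weights_only"`.
#' @param method `"REML"` (default) or `"ML"` estimation of the residual rate
#'   used for coefficient inference. The log-likelihood and AICc reported for
#'   model ranking are always the maximum-likelihood values, since restricted
#'   likelihoods are not comparable across fixed-effect structures.
#' @return An object of class `pgls_fit`: coefficients, their SEs and
#'   covariance, `sigma2` (inference scale), `sigma2_ml`, `logLik` (ML),
#'   `AICc` (with \eqn{k = p + 1} counting the residual rate), `n`, `k`.
#' @export
pgls_fit <- function(y, X, C, se_y, error_model = c("additive", "weights_only"),
                     method = c("REML", "ML")) {
  error_model <- match.arg(error_model)
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(C) == n, ncol(C) == n, length(se_y) == n,
            all(se_y >= 0))
  if (error_model == "weights_only" && any(se_y == 0)) {
    abort("weights_only error model requires strictly positive SEs")
  }
  if (qr(X)$rank < ncol(X)) abort("singular design matrix")
  k <- ncol(X) + 1L
  if (n <= k + 1) abort("too few observations for AICc (need n > k + 1)")
  se2 <- se_y^2
  vy <- var(y)
  if (!is.finite(vy) || vy <= 0) abort("response has no variance")
  lower <- if (any(se2 == 0)) vy * 1e-10 else 0
  profile_max <- function(which_ll) {
    obj <- function(s2) pgls_loglik(s2, y, X, C, se2, error_model)[[which_ll]]
    opt <- optimize(obj, interval = c(lower, 100 * vy), maximum = TRUE,
                    tol = .Machine$double.eps^0.5 * vy)
    # the optimum can sit at the boundary; compare with the boundary value
    cand <- c(opt$maximum, lower)
    cand[which.max(vapply(cand, obj, numeric(1)))]
  }
  sigma2_ml <- profile_max("ll")
  ml <- pgls_loglik(sigma2_ml, y, X, C, se2, error_model)
  if (!is.finite(ml$ll)) abort("PGLS likelihood optimisation failed")
  if (method == "REML") {
    sigma2 <- profile_max("ll_reml")
    sol <- pgls_loglik(sigma2, y, X, C, se2, error_model)
  } else {
    sigma2 <- sigma2_ml
    sol <- ml
  }
  coefs <- setNames(sol$beta, colnames(X))
  ses <- sqrt(diag(sol$vcov))
  aicc <- -2 * ml$ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  structure(list(
    coefficients = coefs, se = setNames(ses, colnames(X)), vcov = sol$vcov,
    sigma2 = sigma2, sigma2_ml = sigma2_ml, logLik = ml$ll, AICc = aicc,
    n = n, k = k, error_model = error_model, method = method,
    terms = colnames(X)
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("<pgls_fit> n = %d, k = %d, sigma2 = %.4g, logLik = %.3f, AICc = %.3f\n",
              x$n, x$k, x$sigma2, x$logLik, x$AICc))
  print(tidy(x))
  invisible(x)
}

#' @rdname pgls_fit
#' @param x A `pgls_fit`.
#' @param conf.level Confidence level. Intervals and p-values use the t
#'   distribution with n - p degrees of freedom, the GLS convention; the
#'   normal approximation slightly undercovers even at n around 100.
#' @param ... Unused.
#' @method tidy pgls_fit
#' @export
tidy.pgls_fit <- function(x, conf.level = 0.95, ...) {
  df <- x$n - (x$k - 1L)
  tq <- stats::qt(1 - (1 - conf.level) / 2, df)
  est <- unname(x$coefficients)
  se <- unname(x$se)
  tibble(
    term = x$terms, estimate = est, std.error = se,
    statistic = est / se,
    p.value = 2 * stats::pt(-abs(est / se), df),
    conf.low = est - tq * se, conf.high = est + tq * se
  )
}

#' @rdname pgls_fit
#' @method glance pgls_fit
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble(sigma2 = x$sigma2, logLik = x$logLik, AICc = x$AICc,
         nobs = x$n, k = x$k, error_model = x$error_model, method = x$method)
}

#' Variance inflation factors and stepwise predictor removal
#'
#' `vif_values()` computes \eqn{VIF_j = 1 / (1 - R_j^2)} for every
#' non-intercept column of a design matrix, \eqn{R_j^2} being from the
#' ordinary regression of column \eqn{j} on the remaining columns (plus an
#' intercept). `vif_filter()` iteratively removes the model *term* owning
#' the single largest VIF above the cutoff (factor dummy blocks leave as a
#' whole; ties broken in favour of the later column) and recomputes until all
#' VIFs are at or below the cutoff.
#'
#' @param X Numeric design matrix without an intercept column.
#' @return `vif_values()`: named numeric vector of VIFs.
#' @export
vif_values <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) return(setNames(rep(1, p), colnames(X)))
  vapply(seq_len(p), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(X))
}

#' @rdname vif_values
#' @param data Data frame holding the predictors.
#' @param terms Character vector of predictor term names (columns of `data`;
#'   factors allowed).
#' @param cutoff VIF threshold (default 5).
#' @return `vif_filter()`: a list with `terms` (retained), `removed`
#'   (in removal order), and `log` (tibble of per-step VIFs).
#' @export
vif_filter <- function(data, terms, cutoff = 5) {
  removed <- character(0)
  log_rows <- list()
  step <- 0L
  while (length(terms) >= 2) {
    mm <- model.matrix(stats::reformulate(terms), data = data)
    assign_map <- attr(mm, "assign")
    X <- mm[, assign_map != 0, drop = FALSE]
    col_term <- terms[assign_map[assign_map != 0]]
    v <- vif_values(X)
    step <- step + 1L
    log_rows[[step]] <- tibble(step = step, column = names(v),
                               term = col_term, vif = unname(v))
    if (all(v <= cutoff)) break
    # worst column; ties broken in favour of the later column
    worst <- max(which(v == max(v)))
    drop_term <- col_term[worst]
    removed <- c(removed, drop_term)
    terms <- setdiff(terms, drop_term)
  }
  list(terms = terms, removed = removed,
       log = if (length(log_rows)) bind_rows(log_rows) else tibble())
}

#' Enumerate nested candidate models
#'
#' All subsets of the (VIF-filtered) global predictor terms, the intercept
#' always included and factor terms entering or leaving whole. Candidates
#' with fewer than `min_samples_per_variable` observations per predictor
#' column are excluded to limit overfitting (the intercept-only model is
#' always admissible).
#'
#' @param terms Character vector of global-model predictor terms.
#' @param data Data frame (used to count dummy columns per term).
#' @param n Number of observations.
#' @param min_samples_per_variable Exclusion floor (default 10).
#' @return A list of character vectors of terms (possibly empty = intercept
#'   only).
#' @export
candidate_models <- function(terms, data, n, min_samples_per_variable = 10) {
  if (length(terms) > 20) abort("more than 20 predictor terms: candidate enumeration refused")
  ncols <- vapply(terms, function(tm) {
    mm <- model.matrix(stats::reformulate(tm), data = data)
    sum(attr(mm, "assign") != 0)
  }, numeric(1))
  subsets <- list(character(0))
  for (tm in terms) {
    subsets <- c(subsets, lapply(subsets, function(s) c(s, tm)))
  }
  keep <- vapply(subsets, function(s) {
    p <- if (length(s) == 0) 0 else sum(ncols[s])
    p == 0 || n / p >= min_samples_per_variable
  }, logical(1))
  out <- subsets[keep]
  if (length(out) == 0) abort("no admissible candidate models")
  out
}

#' AICc model averaging over candidate fits
#'
#' Retains candidates within `window` AICc units of the best model, assigns
#' Akaike weights \eqn{w_i \propto \exp(-\Delta_i/2)} renormalised over the
#' retained set, and averages coefficients. Full (zero-substituted)
#' averaging treats a coefficient as 0 with zero variance in models that
#' exclude it; conditional averaging renormalises over the models containing
#' the term. Unconditional standard errors follow the standard
#' model-averaging formula
#' \eqn{\widehat{se} = \sum_i w_i \sqrt{se_i^2 + (\hat\beta_i - \bar\beta)^2}};
#' 95% CIs use the normal multiplier 1.96 and a term is flagged significant
#' when its CI excludes zero.
#'
#' @param fits List of [pgls_fit()] objects (the candidate fits).
#' @param terms_list List of character term subsets matching `fits`.
#' @param window AICc window (default 2).
#' @param method `"full"` (default) or `"conditional"`.
#' @param conf.level Confidence level (default 0.95).
#' @return An object of class `averaged_model` with `candidates` and
#'   `coefficients` tibbles.
#' @export
model_average <- function(fits, terms_list = NULL, window = 2,
                          method = c("full", "conditional"),
                          conf.level = 0.95) {
  method <- match.arg(method)
  stopifnot(length(fits) >= 1)
  aicc <- vapply(fits, function(f) f$AICc, numeric(1))
  delta <- aicc - min(aicc)
  retained <- delta <= window
  w_raw <- exp(-delta / 2) * retained
  w <- w_raw / sum(w_raw)
  labels <- vapply(seq_along(fits), function(i) {
    tms <- if (!is.null(terms_list)) terms_list[[i]] else
      setdiff(fits[[i]]$terms, "(Intercept)")
    if (length(tms) == 0) "1" else paste(tms, collapse = " + ")
  }, character(1))
  candidates <- tibble(
    model = labels, k = vapply(fits, function(f) f$k, numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    AICc = aicc, delta = delta, weight = ifelse(retained, w, 0),
    retained = retained
  ) %>% arrange(.data$delta)

  idx <- which(retained)
  all_terms <- unique(unlist(lapply(fits[idx], function(f) f$terms)))
  z <- qnorm(1 - (1 - conf.level) / 2)
  coef_rows <- purrr::map(all_terms, function(tm) {
    est_i <- vapply(idx, function(i) {
      if (tm %in% fits[[i]]$terms) unname(fits[[i]]$coefficients[tm]) else 0
    }, numeric(1))
    se_i <- vapply(idx, function(i) {
      if (tm %in% fits[[i]]$terms) unname(fits[[i]]$se[tm]) else 0
    }, numeric(1))
    has <- vapply(idx, function(i) tm %in% fits[[i]]$terms, logical(1))
    wi <- w[idx]
    if (method == "conditional") {
      wi <- wi * has
      wi <- wi / sum(wi)
    }
    est <- sum(wi * est_i)
    se <- sum(wi * sqrt(se_i^2 + (est_i - est)^2))
    tibble(term = tm, estimate = est, std.error = se,
           conf.low = est - z * se, conf.high = est + z * se,
           significant = (est - z * se) > 0 | (est + z * se) < 0,
           n_models = sum(has))
  })
  structure(list(
    candidates = candidates,
    coefficients = bind_rows(coef_rows),
    window = window, method = method, conf.level = conf.level
  ), class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat(sprintf("<averaged_model> %d candidate(s), %d retained (AICc window %.3g, %s averaging)\n",
              nrow(x$candidates), sum(x$candidates$retained), x$window, x$method))
  print(x$coefficients)
  invisible(x)
}

#' @rdname model_average
#' @param x An `averaged_model`.
#' @param ... Unused.
#' @method tidy averaged_model
#' @export
tidy.averaged_model <- function(x, ...) x$coefficients

#' @rdname model_average
#' @method glance averaged_model
#' @export
glance.averaged_model <- function(x, ...) {
  tibble(n_candidates = nrow(x$candidates),
         n_retained = sum(x$candidates$retained),
         best_AICc = min(x$candidates$AICc),
         window = x$window, method = x$method)
}

#' Fit the SE-weighted phylogenetic trait model with model averaging
#'
#' The full inference stage for one analysis table: builds the design from
#' the supplied predictor terms (treatment contrasts, `solo` as the factor
#' reference level where present), applies stepwise VIF filtering at the
#' configured cutoff, enumerates all admissible nested candidate models, fits
#' each by measurement-error PGLS on the pruned tree, and averages the
#' candidates within the AICc window.
#'
#' @param data Analysis tibble with `species`, a response column, an SE
#'   column, and the predictor columns (continuous predictors already
#'   Z-scored).
#' @param tree Phylogeny covering `data$species` (pruned internally).
#' @param predictors Character vector of predictor term names.
#' @param response,se Column names of the response and its SE
#'   (default `displacement_m`, `displacement_se_m`).
#' @param config A [coa_config()].
#' @return A list of class `trait_model`: `global` ([pgls_fit()] of the
#'   VIF-filtered global model), `average` ([model_average()] result), `vif`
#'   (filter log), `marginal_means` (per-level adjusted means for the first
#'   factor predictor, if any), `n`, `predictors`.
#' @export
fit_trait_models <- function(data, tree, predictors,
                             response = "displacement_m",
                             se = "displacement_se_m",
                             config = coa_config()) {
  stopifnot(all(c("species", response, se, predictors) %in% names(data)))
  data <- as.data.frame(data)
  data <- data[match(intersect(tree$tip.label, data$species), data$species), ]
  tr <- prune_tree(tree, data$species)
  C <- brownian_correlation(tr)
  C <- C[data$species, data$species]
  # factor predictors use treatment contrasts with "solo" first where present
  for (tm in predictors) {
    if (is.character(data[[tm]])) data[[tm]] <- factor(data[[tm]])
    if (is.factor(data[[tm]]) && "solo" %in% levels(data[[tm]])) {
      data[[tm]] <- stats::relevel(data[[tm]], ref = "solo")
    }
  }
  y <- data[[response]]
  se_y <- data[[se]]
  n <- length(y)

  vf <- vif_filter(data, predictors, cutoff = config$vif_cutoff)
  make_X <- function(tms) {
    if (length(tms) == 0) {
      matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    } else {
      model.matrix(stats::reformulate(tms), data = data)
    }
  }
  global <- pgls_fit(y, make_X(vf$terms), C, se_y,
                     error_model = config$pgls_error_model)
  cands <- candidate_models(vf$terms, data, n,
                            min_samples_per_variable = config$min_samples_per_variable)
  fits <- lapply(cands, function(tms) {
    pgls_fit(y, make_X(tms), C, se_y, error_model = config$pgls_error_model)
  })
  avg <- model_average(fits, cands, window = config$aicc_window,
                       method = config$averaging)

  factor_terms <- vf$terms[vapply(vf$terms, function(tm) is.factor(data[[tm]]),
                                  logical(1))]
  mm_tab <- if (length(factor_terms) > 0) {
    marginal_means(global, data, factor_terms[1])
  } else NULL

  structure(list(global = global, average = avg, vif = vf,
                 marginal_means = mm_tab, n = n, predictors = predictors,
                 filtered_predictors = vf$terms),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("<trait_model> n = %d species; global terms: %s\n", x$n,
              paste(x$filtered_predictors, collapse = ", ")))
  if (length(x$vif$removed)) {
    cat("VIF-removed:", paste(x$vif$removed, collapse = ", "), "\n")
  }
  print(x$average)
  invisible(x)
}

# Adjusted (marginal) mean response per level of one factor term from the
# global fit: continuous covariates held at 0 (their Z-score mean), other
# factors at their reference level.
marginal_means <- function(fit, data, term) {
  levs <- levels(data[[term]])
  cols <- fit$terms
  L <- matrix(0, length(levs), length(cols), dimnames = list(levs, cols))
  L[, "(Intercept)"] <- 1
  for (lv in levs) {
    dummy <- paste0(term, lv)
    if (dummy %in% cols) L[lv, dummy] <- 1
  }
  est <- as.numeric(L %*% fit$coefficients)
  se <- sqrt(diag(L %*% fit$vcov %*% t(L)))
  tibble(level = levs, mean = est, se = se)
}
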