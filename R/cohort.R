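#' Fit per-age-class latitude-by-day passage curves
#'
#' Fits a penalized thin-plate regression spline of banding latitude on Julian
#' day separately for each age class (HY, AHY) — equivalent to a
#' day-by-age-class interaction smooth — with about 10 basis functions and
#' smoothness chosen by generalized cross-validation, then evaluates both
#' fits on a shared integer day grid.
#'
#' @param records Banding-record tibble for one species.
#' @param window Optional `c(start_day, end_day)` restriction.
#' @param k Spline basis dimension (default 10).
#' @param min_total Minimum total records required (default 1000).
#' @param min_per_class Minimum records per age class within the window
#'   (default 30).
#' @return A list of class `cohort_curves`: `curves` (tibble: `julian_day`,
#'   `age_class`, `fitted`), `n_records` (named count per class), `window`,
#'   and `status` (`"ok"` or `"insufficient_data"`). Record shortfalls yield
#'   an `insufficient_data` status, not an error.
#' @export
fit_age_smoother <- function(records, window = NULL, k = 10,
                             min_total = 1000, min_per_class = 30) {
  stopifnot(all(c("julian_day", "latitude", "age_class") %in% names(records)))
  if (!is.null(window)) {
    records <- filter(records, .data$julian_day >= window[1],
                      .data$julian_day <= window[2])
  }
  n_class <- c(HY = sum(records$age_class == "HY"),
               AHY = sum(records$age_class == "AHY"))
  insufficient <- nrow(records) < min_total || any(n_class < min_per_class)
  if (insufficient) {
    return(structure(list(curves = NULL, n_records = n_class, window = window,
                          status = "insufficient_data"),
                     class = "cohort_curves"))
  }
  day_grid <- seq(min(records$julian_day), max(records$julian_day))
  curves <- purrr::map(c("HY", "AHY"), function(cl) {
    sub <- filter(records, .data$age_class == cl)
    kk <- min(k, length(unique(sub$julian_day)))
    fit <- mgcv::gam(latitude ~ s(julian_day, k = kk), data = sub,
                     method = "GCV.Cp")
    tibble(julian_day = day_grid, age_class = cl,
           fitted = as.numeric(mgcv::predict.gam(
             fit, newdata = data.frame(julian_day = day_grid))))
  }) %>% bind_rows()
  structure(list(curves = curves, n_records = n_class,
                 window = range(day_grid), status = "ok"),
            class = "cohort_curves")
}

#' Detect the autumn migration window from a pooled passage curve
#'
#' Fits a pooled (both age classes) latitude-by-day smooth over the full
#' record range and returns the longest contiguous run of days on which the
#' fitted curve declines faster than `eps` degrees/day, provided the total
#' decline over the run is at least `delta` degrees — an automated stand-in
#' for visually picking the period where latitude shows a clear negative
#' trend. A manual window from configuration can be supplied downstream
#' instead.
#'
#' @param records Banding-record tibble for one species.
#' @param eps Minimum per-day decline (degrees/day, default 0.005).
#' @param delta Minimum total decline over the window (degrees, default 2).
#' @param k Basis dimension of the pooled smooth (default 10).
#' @return A list: `status` (`"ok"`/`"insufficient_data"`) and `window`
#'   (`c(start_day, end_day)` or `NULL`).
#' @export
detect_autumn_window <- function(records, eps = 0.005, delta = 2, k = 10) {
  kk <- min(k, length(unique(records$julian_day)))
  if (kk < 3 || nrow(records) < 10) {
    return(list(status = "insufficient_data", window = NULL))
  }
  fit <- mgcv::gam(latitude ~ s(julian_day, k = kk), data = records,
                   method = "GCV.Cp")
  day_grid <- seq(min(records$julian_day), max(records$julian_day))
  curve <- as.numeric(mgcv::predict.gam(
    fit, newdata = data.frame(julian_day = day_grid)))
  window_from_curve(day_grid, curve, eps = eps, delta = delta)
}

#' @rdname detect_autumn_window
#' @param day Integer day grid.
#' @param value Fitted curve values on `day`.
#' @param edge_tol Plateau tolerance (degrees, default 0.5): the window starts
#'   at the last day still within `edge_tol` of the pre-migration maximum and
#'   ends at the first day within `edge_tol` of the post-migration minimum.
#' @export
window_from_curve <- function(day, value, eps = 0.005, delta = 2,
                              edge_tol = 0.5) {
  stopifnot(length(day) == length(value), length(day) >= 2)
  # descent interval: from the pre-migration maximum to the subsequent
  # minimum, with near-flat plateau edges trimmed at edge_tol. A pooled curve
  # over temporally separated cohorts can rise briefly between the two
  # passage declines (the age-class mixture shifts), so the window must span
  # the whole descent rather than a single monotone run.
  i_max <- which.max(value)
  i_min <- i_max + which.min(value[i_max:length(value)]) - 1L
  if (i_min <= i_max) return(list(status = "insufficient_data", window = NULL))
  if (value[i_max] - value[i_min] < delta) {
    return(list(status = "insufficient_data", window = NULL))
  }
  within_start <- which(value[i_max:i_min] >= value[i_max] - edge_tol)
  s <- i_max + max(within_start) - 1L
  if (s >= i_min) s <- i_max
  within_end <- which(value[s:i_min] <= value[i_min] + edge_tol)
  e <- s + min(within_end) - 1L
  if (e <= s) e <- i_min
  # mean slope over the window must show a clear negative trend
  if ((value[e] - value[s]) / (day[e] - day[s]) > -eps) {
    return(list(status = "insufficient_data", window = NULL))
  }
  list(status = "ok", window = c(day[s], day[e]))
}

# Exact integral of pmin(a, b) treating a and b as piecewise linear between
# grid nodes, splitting segments at crossing points.
integral_min_pl <- function(x, a, b) {
  total <- 0
  for (i in seq_len(length(x) - 1)) {
    x1 <- x[i]; x2 <- x[i + 1]
    d1 <- a[i] - b[i]; d2 <- a[i + 1] - b[i + 1]
    if (d1 * d2 >= 0) {
      lo1 <- min(a[i], b[i]); lo2 <- min(a[i + 1], b[i + 1])
      # when d1*d2 == 0 one endpoint ties; lower envelope is still linear
      if (d1 == 0 && d2 != 0) { lo1 <- a[i]; lo2 <- min(a[i + 1], b[i + 1]) }
      total <- total + (lo1 + lo2) / 2 * (x2 - x1)
    } else {
      t <- d1 / (d1 - d2)
      xc <- x1 + t * (x2 - x1)
      vc <- a[i] + t * (a[i + 1] - a[i])
      lo_left <- if (d1 < 0) a[i] else b[i]
      lo_right <- if (d2 < 0) a[i + 1] else b[i + 1]
      total <- total + (lo_left + vc) / 2 * (xc - x1) +
        (vc + lo_right) / 2 * (x2 - xc)
    }
  }
  total
}

trapz_pl <- function(x, y) sum((head(y, -1) + tail(y, -1)) / 2 * diff(x))

#' Cohort-overlap index between two normalised passage curves
#'
#' Each curve is min-max normalised to \eqn{[0, 1]} over the window, then the
#' proportional overlap in area under the curve is computed. The default form
#' is \eqn{\int \min(\hat f_A, \hat f_B) / \int \max(\hat f_A, \hat f_B)};
#' `method = "min_over_mean"` divides by the mean of the two individual areas
#' instead. Integration is exact for piecewise-linear curves (segments are
#' split at crossing points). The index is symmetric in its arguments and
#' invariant to affine transforms of either raw curve.
#'
#' @param day Shared integer day grid.
#' @param curve_a,curve_b Fitted values on `day`; each must be non-constant.
#' @param method `"min_over_max"` (default) or `"min_over_mean"`.
#' @return Overlap index in \eqn{[0, 1]} (`min_over_mean` can slightly exceed
#'   1 only in degenerate cases; `min_over_max` cannot).
#' @export
#' @examples
#' d <- 1:100
#' overlap_index(d, dnorm(d, 40, 10), dnorm(d, 40, 10)) # identical -> 1
overlap_index <- function(day, curve_a, curve_b,
                          method = c("min_over_max", "min_over_mean")) {
  method <- match.arg(method)
  stopifnot(length(day) == length(curve_a), length(day) == length(curve_b))
  norm01 <- function(v) {
    r <- range(v)
    if (r[2] - r[1] <= 0) abort("degenerate (constant) curve: cannot min-max normalise")
    (v - r[1]) / (r[2] - r[1])
  }
  a <- norm01(curve_a)
  b <- norm01(curve_b)
  i_min <- integral_min_pl(day, a, b)
  i_a <- trapz_pl(day, a)
  i_b <- trapz_pl(day, b)
  denom <- switch(method,
    min_over_max = i_a + i_b - i_min,  # integral of pairwise max
    min_over_mean = (i_a + i_b) / 2
  )
  if (denom <= 0) return(0)
  max(0, min(if (method == "min_over_max") 1 else Inf, i_min / denom))
}

#' Classify cohort migration timing from an overlap index
#'
#' Species whose age-class passage curves overlap strictly more than the
#' threshold are classed as mixed-age migrants; otherwise age-separated.
#'
#' @param overlap Overlap index in \eqn{[0, 1]}.
#' @param threshold Classification threshold (default 0.85; the boundary value
#'   itself classifies as age-separated).
#' @return `"mixed_age"` or `"age_separated"`.
#' @export
classify_cohort_timing <- function(overlap, threshold = 0.85) {
  stopifnot(is.finite(overlap), overlap >= 0, overlap <= 1)
  if (overlap > threshold) "mixed_age" else "age_separated"
}

#' Cohort-timing classification for a set of species
#'
#' Runs the full banding-data procedure per species: pooled full-range smooth
#' to detect the autumn window, per-age-class refits inside the window,
#' min-max normalisation, overlap index, and threshold classification.
#'
#' @param records Banding-record tibble (may hold several species).
#' @param config A [coa_config()].
#' @param window Optional manual `c(start_day, end_day)` override applied to
#'   every species.
#' @return A tibble with one row per species: `window_start`, `window_end`,
#'   `overlap_index`, `n_hy`, `n_ahy`, `classification` (`mixed_age`,
#'   `age_separated`, or `insufficient_data`). The fitted curves are attached
#'   as the `curves` attribute (named list of `cohort_curves`).
#' @export
cohort_overlap <- function(records, config = coa_config(), window = NULL) {
  species_list <- unique(records$species)
  curves_out <- list()
  rows <- purrr::map(species_list, function(sp) {
    sub <- filter(records, .data$species == sp)
    if (nrow(sub) < config$min_banding_records) {
      return(tibble(species = sp, window_start = NA_integer_,
                    window_end = NA_integer_, overlap_index = NA_real_,
                    n_hy = sum(sub$age_class == "HY"),
                    n_ahy = sum(sub$age_class == "AHY"),
                    classification = "insufficient_data"))
    }
    win <- window
    if (is.null(win)) {
      det <- detect_autumn_window(sub)
      if (det$status != "ok") {
        return(tibble(species = sp, window_start = NA_integer_,
                      window_end = NA_integer_, overlap_index = NA_real_,
                      n_hy = sum(sub$age_class == "HY"),
                      n_ahy = sum(sub$age_class == "AHY"),
                      classification = "insufficient_data"))
      }
      win <- det$window
    }
    # the 1000-record floor applies to the species' full record set (checked
    # above); inside the autumn window only the per-class floor matters
    fit <- fit_age_smoother(sub, window = win, min_total = 0,
                            min_per_class = config$min_records_per_class)
    if (fit$status != "ok") {
      return(tibble(species = sp, window_start = win[1], window_end = win[2],
                    overlap_index = NA_real_,
                    n_hy = fit$n_records[["HY"]], n_ahy = fit$n_records[["AHY"]],
                    classification = "insufficient_data"))
    }
    curves_out[[sp]] <<- fit
    wide <- tidyr::pivot_wider(fit$curves, names_from = "age_class",
                               values_from = "fitted")
    ov <- overlap_index(wide$julian_day, wide$HY, wide$AHY,
                        method = config$overlap_method)
    tibble(species = sp, window_start = win[1], window_end = win[2],
           overlap_index = ov,
           n_hy = fit$n_records[["HY"]], n_ahy = fit$n_records[["AHY"]],
           classification = classify_cohort_timing(ov, config$overlap_threshold))
  })
  out <- bind_rows(rows)
  attr(out, "curves") <- curves_out
  out
}
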