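#' Posterior standard deviation from 95th-percentile bounds
#'
#' Approximates the standard deviation of an (approximately normal) posterior
#' from its central 95% interval: \eqn{SD = (hi_{95} - lo_{95})/3.92}, 3.92
#' being twice the 97.5% normal quantile.
#'
#' @param lo95,hi95 Numeric vectors of lower and upper 95th-percentile bounds.
#' @return Numeric vector of standard deviations.
#' @export
#' @examples
#' sd_from_percentiles(8.04, 11.96) # 1
sd_from_percentiles <- function(lo95, hi95) {
  if (any(hi95 < lo95, na.rm = TRUE)) {
    abort("hi95 < lo95: percentile bounds out of order")
  }
  (hi95 - lo95) / 3.92
}

# Abundance-weighted mean of one coordinate axis with first-order Taylor
# propagation. mean = sum(I x)/sum(I); treating stratum posteriors as
# independent, Var(mean) = sum(((x_s - mean)/sum(I))^2 * sd_s^2) because
# d(mean)/d(I_s) = (x_s - mean)/sum(I).
weighted_coa_axis <- function(x, index, index_sd) {
  stopifnot(length(x) == length(index), length(x) == length(index_sd))
  if (any(index < 0) || any(index_sd < 0)) abort("negative index or sd")
  tot <- sum(index)
  if (tot <= 0) return(list(mean = NA_real_, sd = NA_real_))
  m <- sum(index * x) / tot
  v <- sum(((x - m) / tot)^2 * index_sd^2)
  list(mean = m, sd = sqrt(v))
}

#' Annual abundance-weighted centres of abundance
#'
#' For each (species, season, year), the centre of abundance (COA) is the mean
#' of stratum centroid coordinates weighted by the posterior stratum abundance
#' indices, computed separately for longitude and latitude:
#' \deqn{COA = \frac{\sum_s I_s x_s}{\sum_s I_s}.}
#' Uncertainty in each stratum index is propagated by the first-order Taylor
#' (delta) method treating stratum posteriors as independent. Years in which
#' every stratum index is zero have no defined COA; they are returned with
#' `NA` coordinates and flagged `defined = FALSE` (and excluded from trend
#' fitting downstream).
#'
#' @param indices Stratum-index tibble as returned by
#'   [read_stratum_indices()] or [simulate_index_series()]; must contain
#'   `index_sd` (call [read_stratum_indices()] or derive it with
#'   [sd_from_percentiles()]).
#' @return A tibble with one row per (species, season, year): `coa_lon`,
#'   `coa_lat`, `sd_lon`, `sd_lat`, `defined`.
#' @export
annual_coa <- function(indices) {
  stopifnot(all(c("species", "season", "year", "centroid_lon", "centroid_lat",
                  "index_median", "index_sd") %in% names(indices)))
  out <- indices %>%
    group_by(.data$species, .data$season, .data$year) %>%
    summarise(
      coa_lon = weighted_coa_axis(.data$centroid_lon, .data$index_median,
                                  .data$index_sd)$mean,
      sd_lon = weighted_coa_axis(.data$centroid_lon, .data$index_median,
                                 .data$index_sd)$sd,
      coa_lat = weighted_coa_axis(.data$centroid_lat, .data$index_median,
                                  .data$index_sd)$mean,
      sd_lat = weighted_coa_axis(.data$centroid_lat, .data$index_median,
                                 .data$index_sd)$sd,
      .groups = "drop"
    ) %>%
    mutate(defined = is.finite(.data$coa_lon) & is.finite(.data$coa_lat))
  n_undef <- sum(!out$defined)
  if (n_undef > 0) {
    co_log("warn", "coa",
           sprintf("%d year(s) with all-zero indices: COA undefined, excluded from trends",
                   n_undef))
  }
  out
}

# OLS slope of value on year with measurement-error propagation. The slope is
# linear in the values: b = sum(w_n * value_n) with
# w_n = (year_n - mean(year)) / sum((year - mean(year))^2), so
# Var(b) = sum(w_n^2 * value_sd_n^2).
trend_with_error <- function(year, value, value_sd) {
  ok <- is.finite(value)
  year <- year[ok]; value <- value[ok]; value_sd <- value_sd[ok]
  if (length(unique(year)) < 2) {
    abort("need at least 2 distinct years with a defined COA to fit a trend")
  }
  yc <- year - mean(year)
  w <- yc / sum(yc^2)
  list(slope = sum(w * value), se = sqrt(sum(w^2 * value_sd^2)))
}

#' Per-axis linear COA trend with propagated standard error
#'
#' Ordinary least-squares slope of the annual COA coordinate on year,
#' \deqn{b = \frac{\sum_n (Year_n - \overline{Year})(COA_n - \overline{COA})}
#'   {\sum_n (Year_n - \overline{Year})^2},}
#' with the per-year COA standard deviations propagated through the (linear)
#' slope formula. Undefined years are excluded.
#'
#' @param coa Annual COA tibble from [annual_coa()].
#' @param axis `"lat"` or `"lon"`.
#' @return A tibble with one row per (species, season): `trend`, `trend_se`
#'   in degrees per year, and `n_years`.
#' @export
coa_trend <- function(coa, axis = c("lat", "lon")) {
  axis <- match.arg(axis)
  val <- paste0("coa_", axis)
  sdv <- paste0("sd_", axis)
  coa %>%
    group_by(.data$species, .data$season) %>%
    summarise(
      trend = trend_with_error(.data$year, .data[[val]], .data[[sdv]])$slope,
      trend_se = trend_with_error(.data$year, .data[[val]], .data[[sdv]])$se,
      n_years = sum(is.finite(.data[[val]])),
      .groups = "drop"
    ) %>%
    mutate(axis = axis)
}

#' Combined COA displacement from per-axis trends
#'
#' Converts per-axis COA trends (degrees/year) to metres/year — latitude at
#' `degree_metre` metres per degree, longitude additionally scaled by the
#' cosine of the reference latitude — and combines them by the Pythagorean
#' theorem:
#' \deqn{d = \sqrt{a^2 + b^2}, \qquad
#'   \mathrm{Var}(d) = \frac{a^2 \mathrm{Var}(a) + b^2 \mathrm{Var}(b)}{d^2},}
#' treating the two axis trends as independent. At \eqn{d = 0} the delta
#' method degenerates and the SE falls back to
#' \eqn{\sqrt{\mathrm{Var}(a) + \mathrm{Var}(b)}}.
#'
#' @param trend_lat,trend_lon Trends in degrees/year.
#' @param se_lat,se_lon Their standard errors (degrees/year).
#' @param ref_lat Latitude (degrees) at which a degree of longitude is
#'   converted to metres.
#' @param degree_metre Metres per degree of latitude (default 111320).
#' @return A list with `displacement_m`, `displacement_se_m`, and the axis
#'   trends in metres/year (`a_m`, `b_m`, `se_a_m`, `se_b_m`).
#' @export
#' @examples
#' displacement(3 / 111320, 0, 4 / 111320, 0, ref_lat = 0)$displacement_m # 5
displacement <- function(trend_lat, se_lat, trend_lon, se_lon, ref_lat,
                         degree_metre = 111320) {
  stopifnot(is.finite(trend_lat), is.finite(trend_lon),
            is.finite(se_lat), is.finite(se_lon), is.finite(ref_lat))
  a <- trend_lat * degree_metre
  se_a <- se_lat * degree_metre
  lon_scale <- degree_metre * cos(ref_lat * pi / 180)
  b <- trend_lon * lon_scale
  se_b <- se_lon * lon_scale
  d <- sqrt(a^2 + b^2)
  se_d <- if (d > 0) sqrt((a^2 * se_a^2 + b^2 * se_b^2) / d^2) else sqrt(se_a^2 + se_b^2)
  list(displacement_m = d, displacement_se_m = se_d,
       a_m = a, b_m = b, se_a_m = se_a, se_b_m = se_b)
}

#' Species-level COA shift rates
#'
#' End-to-end COA stage: restricts the stratum indices to the configured year
#' window, computes annual weighted COAs with propagated uncertainty, fits
#' per-axis linear trends, and combines them into a single displacement vector
#' in metres/year with its propagated standard error and the reciprocal-SE
#' weight used by the downstream phylogenetic regression.
#'
#' @param indices Stratum-index tibble (with `index_sd`).
#' @param config A [coa_config()].
#' @return A list with `shift` (one row per species x season: per-axis trends
#'   and SEs in degrees/year, `displacement_m`, `displacement_se_m`, `weight`)
#'   and `coa` (the annual COA table).
#' @export
species_shift <- function(indices, config = coa_config()) {
  idx <- filter(indices, .data$year >= config$year_start,
                .data$year <= config$year_end)
  if (nrow(idx) == 0) abort("no index rows inside the configured year window")
  coa <- annual_coa(idx)
  tl <- coa_trend(coa, "lat")
  tg <- coa_trend(coa, "lon")
  mean_lat <- coa %>%
    filter(.data$defined) %>%
    group_by(.data$species, .data$season) %>%
    summarise(mean_coa_lat = mean(.data$coa_lat), .groups = "drop")
  shift <- tl %>%
    select("species", "season", trend_lat = "trend", trend_lat_se = "trend_se",
           "n_years") %>%
    left_join(select(tg, "species", "season", trend_lon = "trend",
                     trend_lon_se = "trend_se"),
              by = c("species", "season")) %>%
    left_join(mean_lat, by = c("species", "season"))
  ref <- function(mean_coa_lat) {
    if (identical(config$lon_reference_lat, "mean_coa")) mean_coa_lat
    else as.numeric(config$lon_reference_lat)
  }
  disp <- purrr::pmap(
    list(shift$trend_lat, shift$trend_lat_se, shift$trend_lon,
         shift$trend_lon_se, shift$mean_coa_lat),
    function(tl, sl, tg2, sg, ml) {
      displacement(tl, sl, tg2, sg, ref_lat = ref(ml),
                   degree_metre = config$degree_metre)
    }
  )
  shift <- shift %>%
    mutate(
      displacement_m = purrr::map_dbl(disp, "displacement_m"),
      displacement_se_m = purrr::map_dbl(disp, "displacement_se_m"),
      weight = 1 / .data$displacement_se_m
    )
  list(shift = shift, coa = coa)
}
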