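#' Pipeline run configuration
#'
#' Bundles the tunable thresholds of the analysis: the year window over which
#' centre-of-abundance (COA) trends are estimated, the cohort-overlap threshold
#' separating mixed-age from age-separated migration timing, the travelling
#' flock-size threshold defining a flocking species, the variance-inflation
#' cutoff for predictor removal, the AICc window for model averaging, and the
#' samples-per-variable floor that guards against overfitting.
#'
#' @param year_start,year_end Integer bounds of the analysis window
#'   (inclusive). The default window 1970-2019 avoids the early survey years
#'   with sparse spatial coverage.
#' @param overlap_threshold Cohort-overlap index above which (strictly) a
#'   species is classed as a mixed-age migrant. Default 0.85.
#' @param flocking_size_threshold Maximum travelling flock size above which
#'   (strictly) a species is classed as flocking. Default 2; 5 and 10 are the
#'   conventional sensitivity settings.
#' @param vif_cutoff Variance-inflation-factor threshold for stepwise predictor
#'   removal. Default 5.
#' @param aicc_window Candidate models within this many AICc units of the best
#'   model are retained for averaging. Default 2.
#' @param min_samples_per_variable Candidate models with fewer than this many
#'   observations per predictor column are excluded. Default 10.
#' @param min_banding_records Minimum total banding records for a species to
#'   enter the cohort-timing analysis. Default 1000.
#' @param min_records_per_class Minimum banding records per age class inside
#'   the autumn window. Default 30.
#' @param degree_metre Metres per degree of latitude used to express COA trends
#'   in metres per year; longitude is additionally scaled by the cosine of the
#'   species' mean COA latitude. Default 111320.
#' @param lon_reference_lat Either `"mean_coa"` (default: cosine correction at
#'   the species' mean COA latitude) or a fixed numeric reference latitude in
#'   degrees (equirectangular sensitivity mode).
#' @param overlap_method `"min_over_max"` (default) or `"min_over_mean"`:
#'   whether the overlap index divides the integrated minimum of the two
#'   normalised curves by the integrated maximum or by the mean of the two
#'   individual areas.
#' @param pgls_error_model `"additive"` (default; residual covariance
#'   \eqn{\sigma^2 C + \mathrm{diag}(SE^2)}) or `"weights_only"` (pure
#'   reciprocal-variance weighting, no phylogenetic term).
#' @param averaging `"full"` (default; zero-substituted) or `"conditional"`.
#' @param seed Integer seed recorded in run manifests.
#'
#' @return A list of class `coa_config`.
#' @export
#' @examples
#' cfg <- coa_config(year_start = 1980, year_end = 2019)
#' cfg$overlap_threshold
coa_config <- function(year_start = 1970L,
                       year_end = 2019L,
                       overlap_threshold = 0.85,
                       flocking_size_threshold = 2L,
                       vif_cutoff = 5,
                       aicc_window = 2,
                       min_samples_per_variable = 10L,
                       min_banding_records = 1000L,
                       min_records_per_class = 30L,
                       degree_metre = 111320,
                       lon_reference_lat = "mean_coa",
                       overlap_method = c("min_over_max", "min_over_mean"),
                       pgls_error_model = c("additive", "weights_only"),
                       averaging = c("full", "conditional"),
                       seed = 1L) {
  overlap_method <- match.arg(overlap_method)
  pgls_error_model <- match.arg(pgls_error_model)
  averaging <- match.arg(averaging)
  stopifnot(
    is.numeric(year_start), is.numeric(year_end), year_start < year_end,
    overlap_threshold > 0, flocking_size_threshold > 0, vif_cutoff > 0,
    aicc_window > 0, min_samples_per_variable > 0, degree_metre > 0
  )
  structure(list(
    year_start = as.integer(year_start),
    year_end = as.integer(year_end),
    overlap_threshold = overlap_threshold,
    flocking_size_threshold = as.integer(flocking_size_threshold),
    vif_cutoff = vif_cutoff,
    aicc_window = aicc_window,
    min_samples_per_variable = as.integer(min_samples_per_variable),
    min_banding_records = as.integer(min_banding_records),
    min_records_per_class = as.integer(min_records_per_class),
    degree_metre = degree_metre,
    lon_reference_lat = lon_reference_lat,
    overlap_method = overlap_method,
    pgls_error_model = pgls_error_model,
    averaging = averaging,
    seed = as.integer(seed)
  ), class = "coa_config")
}

#' Read or write a run configuration as YAML
#'
#' @param path File path.
#' @return `read_config()` returns a [coa_config()]; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(coa_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(coa_config, vals)
}

#' @rdname read_config
#' @param config A [coa_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "coa_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.coa_config <- function(x, ...) {
  cat("<coa_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
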