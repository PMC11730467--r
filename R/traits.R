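#' Flocking classification from maximum travelling flock size
#'
#' A species is classed as flocking when its maximum reported travelling
#' flock size strictly exceeds the threshold (default 2; 5 and 10 are the
#' conventional sensitivity settings). `flock_size_category()` refines this
#' into solo (size <= 2), small flocks (3-9), and large flocks (>= 10; the
#' ambiguous boundary value 10 is assigned to large).
#'
#' @param size Integer maximum travelling flock size (>= 1); vectorised.
#' @param threshold Flocking threshold (default 2, strict `>`).
#' @return `classify_flocking()`: `"flocking"`/`"solo"`;
#'   `flock_size_category()`: `"solo"`/`"small"`/`"large"`.
#' @export
#' @examples
#' classify_flocking(c(2, 3, 7), threshold = 2)
#' flock_size_category(c(1, 5, 10))
classify_flocking <- function(size, threshold = 2) {
  if (any(size < 1)) abort("flock size must be a positive count")
  ifelse(size > threshold, "flocking", "solo")
}

#' @rdname classify_flocking
#' @export
flock_size_category <- function(size) {
  if (any(size < 1)) abort("flock size must be a positive count")
  dplyr::case_when(size <= 2 ~ "solo", size < 10 ~ "small", TRUE ~ "large")
}

#' Combine binary flocking with cohort timing
#'
#' Solo migrants stay solo regardless of cohort timing; flocking species are
#' split into mixed-age or age-separated flocks by the cohort classification.
#' `insufficient_data` cohort results propagate, marking species that can
#' enter the binary-flocking model pool (Model A) but not the refined
#' three-level pool (Model B).
#'
#' @param flocking_binary `"flocking"` or `"solo"`; vectorised.
#' @param cohort_classification `"mixed_age"`, `"age_separated"`, or
#'   `"insufficient_data"`.
#' @return `"solo"`, `"mixed_age_flocks"`, `"age_separated_flocks"`, or
#'   `"insufficient_data"`.
#' @export
combine_flocking_behaviour <- function(flocking_binary, cohort_classification) {
  dplyr::case_when(
    flocking_binary == "solo" ~ "solo",
    cohort_classification == "mixed_age" ~ "mixed_age_flocks",
    cohort_classification == "age_separated" ~ "age_separated_flocks",
    TRUE ~ "insufficient_data"
  )
}

#' Great-circle migration distance between seasonal range centroids
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the mean Earth
#' radius).
#'
#' @param lon1,lat1 Breeding-range centroid (decimal degrees).
#' @param lon2,lat2 Non-breeding-range centroid.
#' @return Distance in kilometres.
#' @export
#' @examples
#' migration_distance(0, 0, 180, 0) # half the circumference, ~20015 km
migration_distance <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    abort("coordinates outside WGS84 bounds")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088e3) / 1000
}

#' Absolute population trend
#'
#' @param trend Signed population trend (percent/year).
#' @return `abs(trend)`.
#' @export
absolute_trend <- function(trend) {
  stopifnot(all(is.finite(trend)))
  abs(trend)
}

#' Standardize numeric columns to Z-scores
#'
#' Centres and scales the named columns using the sample standard deviation
#' (n - 1 denominator). The means and SDs are recorded in the `scaling`
#' attribute so model coefficients can be back-transformed to the original
#' units (metres/year per original unit rather than per SD).
#'
#' @param data A data frame.
#' @param cols Character vector of numeric column names.
#' @return `data` with the columns standardized; attribute `scaling` is a
#'   tibble (`column`, `mean`, `sd`).
#' @export
zscore_columns <- function(data, cols) {
  stopifnot(all(cols %in% names(data)))
  scaling <- purrr::map(cols, function(cl) {
    x <- data[[cl]]
    if (!is.numeric(x)) abort(paste0("column is not numeric: ", cl))
    s <- sd(x)
    if (!is.finite(s) || s <= 0) abort(paste0("zero-variance column: ", cl))
    tibble(column = cl, mean = mean(x), sd = s)
  }) %>% bind_rows()
  for (i in seq_len(nrow(scaling))) {
    cl <- scaling$column[i]
    data[[cl]] <- (data[[cl]] - scaling$mean[i]) / scaling$sd[i]
  }
  attr(data, "scaling") <- scaling
  data
}

#' Assemble the analysis-ready species table
#'
#' Merges the COA shift table (response: displacement and its SE), the
#' cohort-timing classifications, and the trait table into one row per
#' species, derives the combined flocking-behaviour factor, takes the
#' absolute population trend, and Z-scores the continuous predictors. Two
#' model pools are flagged: Model A (binary flocking; every species with a
#' flocking classification) and Model B (three-level behaviour; the subset
#' with a resolved cohort timing). Species with missing predictor values are
#' dropped with a logged tally.
#'
#' @param shift COA shift tibble from [species_shift()] (one season).
#' @param cohort Cohort-timing tibble from [cohort_overlap()], or `NULL` if
#'   behaviour is already present in `traits`.
#' @param traits Trait tibble with at least `species`, `flocking_binary`, and
#'   the continuous predictor columns.
#' @param predictors Character vector of continuous predictor columns to
#'   Z-score.
#' @return A tibble with `in_model_a`/`in_model_b` flags and a `scaling`
#'   attribute from [zscore_columns()].
#' @export
assemble_traits <- function(shift, cohort, traits,
                            predictors = intersect(
                              c("migration_distance_km", "generation_length_yr",
                                "habitat_specialism", "diet_specialism",
                                "abs_population_trend", "total_range_km2",
                                "sampled_range_km2"),
                              names(traits))) {
  out <- traits
  if (!is.null(cohort)) {
    out <- left_join(out,
                     select(cohort, "species", cohort_class = "classification"),
                     by = "species") %>%
      mutate(cohort_class = tidyr::replace_na(.data$cohort_class,
                                              "insufficient_data"),
             flocking_behaviour = combine_flocking_behaviour(
               as.character(.data$flocking_binary), .data$cohort_class))
  } else if (!"flocking_behaviour" %in% names(out)) {
    abort("supply either a cohort table or a flocking_behaviour column")
  }
  if ("population_trend" %in% names(out) &&
      !"abs_population_trend" %in% names(out)) {
    out <- mutate(out, abs_population_trend = absolute_trend(.data$population_trend))
  }
  out <- left_join(select(shift, "species", "displacement_m",
                          "displacement_se_m", "weight"),
                   out, by = "species",
                   suffix = c("", ".trait"))
  complete_pred <- complete.cases(out[, predictors, drop = FALSE])
  n_drop <- sum(!complete_pred)
  if (n_drop > 0) {
    co_log("warn", "traits",
           sprintf("dropping %d species with missing predictor values", n_drop))
  }
  out <- out[complete_pred, , drop = FALSE]
  out <- mutate(out,
    in_model_a = !is.na(.data$flocking_binary),
    in_model_b = !is.na(.data$flocking_behaviour) &
      as.character(.data$flocking_behaviour) != "insufficient_data"
  )
  if (length(predictors) > 0) out <- zscore_columns(out, predictors)
  out
}
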