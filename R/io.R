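#' Read stratum-level annual abundance index posteriors
#'
#' Reads the tabular output of the upstream hierarchical survey-index models:
#' one row per (species, season, stratum, year) carrying the stratum centroid
#' and the posterior median and 95th-percentile bounds of the abundance index.
#' The posterior standard deviation is derived on read as
#' \deqn{SD = (\mathrm{hi}_{95} - \mathrm{lo}_{95}) / 3.92,}
#' the normal approximation to a posterior from its central 95% interval.
#'
#' @param path CSV file with columns `species`, `season`, `stratum_id`,
#'   `centroid_lon`, `centroid_lat`, `year`, `index_median`, `index_lo95`,
#'   `index_hi95`.
#' @return A tibble with the input columns plus derived `index_sd`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' scn <- sim_scenario(n_species = 1, n_strata = 9, n_years = 3)
#' write_stratum_indices(simulate_index_series(scn, "sp01"), tf)
#' idx <- read_stratum_indices(tf)
#' head(idx)
read_stratum_indices <- function(path) {
  required <- c("species", "season", "stratum_id", "centroid_lon",
                "centroid_lat", "year", "index_median", "index_lo95",
                "index_hi95")
  x <- read_checked_csv(path, required, module = "io")
  x <- mutate(x,
    season = as.character(season),
    stratum_id = as.character(stratum_id),
    year = as.integer(year)
  )
  bad_season <- setdiff(unique(x$season), c("breeding", "nonbreeding"))
  if (length(bad_season) > 0) {
    abort(paste0("unknown season level(s): ", paste(bad_season, collapse = ", ")))
  }
  bad_order <- which(x$index_lo95 > x$index_hi95 |
                       x$index_median < x$index_lo95 |
                       x$index_median > x$index_hi95)
  if (length(bad_order) > 0) {
    abort(paste0("index percentile ordering violated (lo95 <= median <= hi95) at row(s): ",
                 paste(head(bad_order, 5), collapse = ", ")))
  }
  if (any(x$index_lo95 < 0)) abort("negative abundance index bound")
  if (any(abs(x$centroid_lat) > 90) || any(abs(x$centroid_lon) > 180)) {
    abort("stratum centroid outside WGS84 bounds")
  }
  dup <- x %>%
    count(.data$species, .data$season, .data$stratum_id, .data$year) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate (species, season, stratum, year) rows, e.g. ",
                 dup$species[1], "/", dup$season[1], "/", dup$stratum_id[1],
                 "/", dup$year[1]))
  }
  mutate(x, index_sd = sd_from_percentiles(.data$index_lo95, .data$index_hi95))
}

#' @rdname read_stratum_indices
#' @param x A stratum-index tibble (the derived `index_sd` column, if present,
#'   is dropped on write and re-derived on read).
#' @export
write_stratum_indices <- function(x, path) {
  keep <- c("species", "season", "stratum_id", "centroid_lon", "centroid_lat",
            "year", "index_median", "index_lo95", "index_hi95")
  readr::write_csv(select(x, all_of(keep)), path)
  invisible(path)
}

#' Read banding-event records
#'
#' Reads opportunistic banding records (species, Julian day, latitude of the
#' banding event, and age class: hatch-year `HY` or after-hatch-year `AHY`).
#' Rows with a day outside 1-366, an unknown age code, or a latitude outside
#' \eqn{[-90, 90]} are dropped with a logged tally rather than raising an
#' error, mirroring the quality profile of opportunistic banding data.
#'
#' @param path CSV file with columns `species`, `julian_day`, `latitude`,
#'   `age_class`.
#' @return A tibble of validated records.
#' @export
read_banding <- function(path) {
  required <- c("species", "julian_day", "latitude", "age_class")
  x <- read_checked_csv(path, required, module = "io")
  x <- mutate(x, julian_day = suppressWarnings(as.integer(julian_day)),
              age_class = as.character(age_class))
  ok <- !is.na(x$julian_day) & x$julian_day >= 1 & x$julian_day <= 366 &
    x$age_class %in% c("HY", "AHY") &
    is.finite(x$latitude) & abs(x$latitude) <= 90
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    co_log("warn", "io", sprintf("dropped %d invalid banding row(s) of %d",
                                 n_drop, nrow(x)))
  }
  x <- x[ok, , drop = FALSE]
  if (nrow(x) == 0) abort("no valid banding records after filtering")
  as_tibble(x)
}

#' @rdname read_banding
#' @param x A banding-record tibble.
#' @export
write_banding <- function(x, path) {
  keep <- c("species", "julian_day", "latitude", "age_class")
  readr::write_csv(select(x, all_of(keep)), path)
  invisible(path)
}

#' Read, write and prune phylogenetic trees
#'
#' Thin wrappers around \pkg{ape}'s Newick parser that add the validation this
#' pipeline needs: a rooted tree with branch lengths and unique tip labels.
#' `prune_tree()` returns the induced subtree on a requested species set and
#' errors informatively when tips are missing; pruning preserves patristic
#' distances among the retained tips.
#'
#' @param path Newick file.
#' @return `read_tree()` returns an \pkg{ape} `phylo` object.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "(A:1,(B:0.5,C:0.5):0.5);")
#' prune_tree(tr, c("A", "B"))
read_tree <- function(path) {
  if (!file.exists(path)) abort(paste0("tree file not found: ", path))
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort(paste0("could not parse Newick file: ", path))
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(tree$edge.length < 0)) abort("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) abort("duplicate tip labels in tree")
  tree
}

#' @rdname read_tree
#' @param tree A `phylo` object.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname read_tree
#' @param species Character vector of tip labels to retain.
#' @export
prune_tree <- function(tree, species) {
  missing <- setdiff(species, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("species absent from tree: ", paste(missing, collapse = ", ")))
  }
  if (setequal(species, tree$tip.label)) return(tree)
  ape::keep.tip(tree, species)
}

# Shared CSV reader with schema validation.
read_checked_csv <- function(path, required, module = "io") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  co_log("info", module, sprintf("read %d rows from %s", nrow(x), basename(path)))
  x
}
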