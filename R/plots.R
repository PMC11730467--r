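#' Plot an annual COA trajectory
#'
#' Longitude-latitude path of the annual centres of abundance for one or more
#' species, coloured by year, with one panel per species x season.
#'
#' @param coa Annual COA tibble from [annual_coa()].
#' @return A ggplot object.
#' @export
plot_coa_trajectory <- function(coa) {
  coa <- filter(coa, .data$defined)
  ggplot2::ggplot(coa, ggplot2::aes(.data$coa_lon, .data$coa_lat,
                                    colour = .data$year)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~ species + season, scales = "free") +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "COA longitude (°)", y = "COA latitude (°)",
                  colour = "Year") +
    ggplot2::theme_minimal()
}

#' @rdname fit_age_smoother
#' @param object A `cohort_curves` object.
#' @param records Optional raw banding records to underlay as points.
#' @param ... Unused.
#' @method autoplot cohort_curves
#' @export
autoplot.cohort_curves <- function(object, records = NULL, ...) {
  if (object$status != "ok") abort("nothing to plot: insufficient data")
  p <- ggplot2::ggplot()
  if (!is.null(records)) {
    p <- p + ggplot2::geom_point(
      data = records,
      ggplot2::aes(.data$julian_day, .data$latitude, colour = .data$age_class),
      alpha = 0.15, size = 0.4)
  }
  p +
    ggplot2::geom_line(data = object$curves,
                       ggplot2::aes(.data$julian_day, .data$fitted,
                                    colour = .data$age_class),
                       linewidth = 1) +
    ggplot2::labs(x = "Julian day", y = "Latitude (°)",
                  colour = "Age class") +
    ggplot2::theme_minimal()
}

#' @rdname model_average
#' @param object An `averaged_model`.
#' @method autoplot averaged_model
#' @export
autoplot.averaged_model <- function(object, ...) {
  co <- filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(co, ggplot2::aes(.data$estimate, .data$term,
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red3", `FALSE` = "grey30"),
                                 guide = "none") +
    ggplot2::labs(x = "Model-averaged coefficient (m/yr)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname fit_trait_models
#' @param object A `trait_model`.
#' @param ... Unused.
#' @method autoplot trait_model
#' @export
autoplot.trait_model <- function(object, ...) {
  if (is.null(object$marginal_means)) return(autoplot.averaged_model(object$average))
  mm <- object$marginal_means
  ggplot2::ggplot(mm, ggplot2::aes(.data$level, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = "Adjusted mean COA shift (m/yr)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
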