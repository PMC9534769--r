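#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Taylor term series
#'
#' Monthly driver contributions to the pCO2 anomaly, with the reconstructed
#' (and, if available, actual) total overlaid.
#'
#' @param object A `term_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.term_series <- function(object, ...) {
  long <- tidy(object)
  totals <- long[long$term %in% c("reconstructed_total", "actual_total"), ]
  terms <- long[!long$term %in% c("reconstructed_total", "actual_total"), ]
  ggplot2::ggplot(terms, ggplot2::aes(x = .data$month, y = .data$value,
                                      colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = totals,
                       ggplot2::aes(linetype = .data$term), colour = "black") +
    ggplot2::scale_x_continuous(breaks = seq(1, 12, 2)) +
    ggplot2::labs(x = "month", y = "pCO2 anomaly contribution (uatm)",
                  colour = "term", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a climate-CO2 separation
#'
#' @param object A `pco2_separation`.
#' @param ... Unused.
#' @return A ggplot of the modern/future anomalies and the separation
#'   components.
#' @export
autoplot.pco2_separation <- function(object, ...) {
  long <- tidy(object)
  keep <- c("modern", "future", "delta_sens", "delta_anom_star")
  long <- long[long$component %in% keep, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$month, y = .data$value,
                                     colour = .data$component,
                                     linetype = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = seq(1, 12, 2)) +
    ggplot2::labs(x = "month", y = "pCO2 anomaly (uatm)") +
    ggplot2::theme_minimal()
}

#' Plot a timing curve
#'
#' Months of the annual high and low of the basin-mean pCO2 anomaly as a
#' function of atmospheric CO2 (raw points and smoothed curves).
#'
#' @param object A `timing_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.timing_curve <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$co2_ppm, colour = .data$extreme)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$month_raw), alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$month_smooth)) +
    ggplot2::scale_y_continuous(breaks = 1:12, limits = c(1, 13)) +
    ggplot2::labs(x = "atmospheric CO2 (ppm)", y = "month of extreme") +
    ggplot2::theme_minimal()
}

#' Plot the annual-cycle evolution across CO2 levels
#'
#' @param levels_data Tibble with `co2_ppm`, `month`, `anom` (12 rows per
#'   level), as produced by the pipeline's timing stage.
#' @return A ggplot with one line per CO2 level.
#' @export
plot_cycle_evolution <- function(levels_data) {
  ggplot2::ggplot(levels_data,
                  ggplot2::aes(x = .data$month, y = .data$anom,
                               group = .data$co2_ppm, colour = .data$co2_ppm)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = seq(1, 12, 2)) +
    ggplot2::scale_colour_viridis_c(name = "CO2 (ppm)") +
    ggplot2::labs(x = "month", y = "pCO2 anomaly (uatm)") +
    ggplot2::theme_minimal()
}
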