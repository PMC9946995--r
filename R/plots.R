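# ggplot2 visualisations for the main result types.

#' Map a per-pixel or per-cell value on the grid
#'
#' @param data Tibble with `row`, `col` and a value column.
#' @param value Column to map.
#' @return A ggplot object (tile map).
#' @export
plot_score_map <- function(data, value = "bg_score") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = value) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Class medians of the score series over time
#'
#' @param data Coarse score tibble.
#' @param classes Tertile classification from [classify_tertiles()].
#' @param value Score column.
#' @return A ggplot object.
#' @export
plot_class_series <- function(data, classes, value = "bg_score") {
  df <- dplyr::inner_join(data, dplyr::select(classes, "cell_id", "class"),
                          by = "cell_id") |>
    dplyr::summarise(median = stats::median(.data[[value]], na.rm = TRUE),
                     .by = c("year", "class"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$median,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(y = sprintf("median %s", value), colour = "degradation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of the spatial-model fixed effects
#'
#' @param object An `rw_spatial_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rw_spatial_fit <- function(object, ...) {
  df <- object$coefficients
  df <- df[df$term != "(Intercept)", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term,
                                   colour = .data$supported)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::labs(x = "effect on degradation rate", y = NULL,
                  colour = "interval excludes 0") +
    ggplot2::theme_minimal()
}

#' Per-class shock or recovery distributions
#'
#' @param object An `rw_class_stats` (from [resistance_by_class()] or
#'   [recovery_by_class()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rw_class_stats <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$class, y = .data$median)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::labs(y = object$metric,
                  title = sprintf("shock year %d", object$shock_year)) +
    ggplot2::theme_minimal()
}

#' PIT histogram for a calibration check
#'
#' @param object An `rw_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rw_calibration <- function(object, ...) {
  ggplot2::ggplot(object$histogram, ggplot2::aes(x = .data$mid,
                                                 y = .data$count)) +
    ggplot2::geom_col(width = 1 / nrow(object$histogram)) +
    ggplot2::labs(x = "PIT value", y = "count",
                  subtitle = sprintf("KS distance from uniform: %.3f",
                                     object$ks_distance)) +
    ggplot2::theme_minimal()
}
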