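# Diagnostic plots. All return ggplot objects.

#' Plot per-group phagocytosis metrics
#'
#' Group means (bars) with per-sample points for a chosen metric of a
#' [phagocytosis_summary()] table.
#'
#' @param summary Output of [phagocytosis_summary()].
#' @param metric Column to plot (default `ph_index`).
#' @return A ggplot.
#' @export
plot_phagocytosis <- function(summary, metric = "ph_index") {
  if (!metric %in% names(summary)) {
    abort_validation("Metric '", metric, "' not in summary.")
  }
  df <- summary[!is.na(summary[[metric]]), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data[[metric]])) +
    ggplot2::stat_summary(fun = mean, geom = "col", width = 0.6,
                          fill = "grey80", colour = "grey30") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Plot a distance-to-process histogram
#'
#' @param histogram Output of [distance_histogram()].
#' @return A ggplot of per-bin proportions (in %).
#' @export
plot_distance_histogram <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = factor(.data$label, levels = .data$label),
                               y = 100 * .data$prop)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "Distance to nearest microglial process (µm)",
                  y = "Apoptotic cells (%)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-phagoquant
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot()` for a [motility_trace()] / [measure_process()] result draws
#' the per-frame length trace; for a [efficiency_from_dilutions()] model it
#' draws the standard curve with its fit.
#'
#' @param object A `motility_trace`, `process_measurement`, or
#'   `qpcr_efficiency`.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot-phagoquant
NULL

#' @rdname autoplot-phagoquant
#' @export
autoplot.motility_trace <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$length_um)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "Frame", y = "Process length (µm)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-phagoquant
#' @export
autoplot.process_measurement <- function(object, ...) {
  autoplot.motility_trace(object$trace, ...)
}

#' @rdname autoplot-phagoquant
#' @export
autoplot.qpcr_efficiency <- function(object, ...) {
  ggplot2::ggplot(data.frame(x = 0), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::labs(
      x = "log10 relative concentration", y = "Ct",
      title = sprintf("eff = %.3f, slope = %.3f, r² = %.4f",
                      object$efficiency, object$slope, object$r_squared)
    ) +
    ggplot2::xlim(-4, 0.5) +
    ggplot2::theme_minimal()
}
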