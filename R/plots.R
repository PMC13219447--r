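#' Plot a chromatogram with its called peaks
#'
#' @param trace data frame with `migration` and `rfu`.
#' @param peaks optional peaks tibble (e.g. `tidy()` of an
#'   [idaa_pipeline()] result); classified peaks are coloured by class.
#' @return a ggplot object.
#' @export
plot_chromatogram <- function(trace, peaks = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(.data$migration, .data$rfu)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "migration (scan units)", y = "signal (RFU)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    if ("class" %in% names(peaks)) {
      p <- p + ggplot2::geom_point(
        data = peaks,
        ggplot2::aes(.data$apex_migration, .data$height, colour = .data$class)
      ) + ggplot2::labs(colour = "outcome")
    } else {
      p <- p + ggplot2::geom_point(
        data = peaks, ggplot2::aes(.data$apex_migration, .data$height))
    }
  }
  p
}

#' @rdname wound_closure_series
#' @param object a `wound_series` tibble.
#' @param ... unused.
#' @export
autoplot.wound_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t, .data$closure)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "time (h)", y = "wound closure (%)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a gating step
#'
#' @param gated output of [gate_chain()].
#' @param x,y channel names.
#' @param gate name of the logical gate column to colour by, default
#'   `"in_analysis"`.
#' @param log_scale log10 both axes (the flow-cytometry convention).
#' @return a ggplot object.
#' @export
plot_gate <- function(gated, x = "FSC_A", y = "SSC_A",
                      gate = "in_analysis", log_scale = TRUE) {
  stopifnot(all(c(x, y, gate) %in% names(gated)))
  p <- ggplot2::ggplot(gated, ggplot2::aes(.data[[x]], .data[[y]],
                                           colour = .data[[gate]])) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::labs(colour = gate) +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
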