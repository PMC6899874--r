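# ggplot2 displays for band objects and reports.

band_plot <- function(bands, windows = NULL, xlab, ylab, hline = NULL) {
  df <- as_tibble(bands)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s))
  if (!is.null(windows) && nrow(windows$windows) > 0) {
    w <- windows$windows
    p <- p + ggplot2::annotate("rect", xmin = w$start_s, xmax = w$end_s,
                               ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "grey40")
  }
  if (!is.null(hline)) {
    p <- p + ggplot2::geom_hline(yintercept = hline, linetype = "dashed",
                                 colour = "grey60")
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi,
                                      fill = .data$condition), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$group_median,
                                    colour = .data$condition)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$group_median,
                                     colour = .data$condition), size = 0.8) +
    ggplot2::labs(x = xlab, y = ylab, colour = "condition", fill = "condition") +
    ggplot2::theme_minimal()
}

#' Plot blinding bands
#'
#' Median weighted detection scores per probe with their bootstrap bands,
#' one ribbon per condition; windows of non-overlap can be highlighted.
#'
#' @param object A [probe_bands()] result.
#' @param windows Optional [distinct_windows()] result to highlight.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.blinding_bands <- function(object, windows = NULL, ...) {
  band_plot(object, windows,
            xlab = "time since ramp-up onset (s)",
            ylab = "weighted detection score (-10 off ... +10 on)",
            hline = 0)
}

#' Plot the sub-block reaction-time bands
#'
#' @param object A `subblock_bands` tibble from [subblock_timecourse()].
#' @param windows Optional [distinct_windows()] result to highlight.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.subblock_bands <- function(object, windows = NULL, ...) {
  band_plot(object, windows,
            xlab = "time since ramp-up onset (s)",
            ylab = "median reaction time (ms)")
}

#' @export
plot.sham_report <- function(x, ...) {
  print(autoplot(x$blinding$bands, x$blinding$windows))
  invisible(x)
}
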