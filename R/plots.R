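#' Plot a decoded trajectory against the ground truth
#'
#' One panel per state dimension, estimate over time with the truth overlaid
#' (when available).
#'
#' @param object a `decoding_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.decoding_result <- function(object, ...) {
  long <- tidy(object)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate, colour = "estimate")) +
    ggplot2::facet_wrap(~dim, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time bin", y = "state",
                  colour = NULL,
                  title = paste0("Decoded trajectory (",
                                 attr(object, "method"), ")")) +
    ggplot2::theme_minimal()
  if ("truth" %in% names(long)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$truth, colour = "truth"),
                                linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot error and iteration count against kernel bandwidth
#'
#' Companion plot for the `bandwidth_sweep` experiment: decoding error and
#' median fixed-point iterations per bandwidth (log-x).
#'
#' @param report an `experiment_report` from
#'   `run_experiment("bandwidth_sweep", ...)`.
#' @return a ggplot.
#' @export
plot_bandwidth_sweep <- function(report) {
  stopifnot(inherits(report, "experiment_report"), !is.null(report$sweep))
  long <- tidyr::pivot_longer(report$sweep[c("sigma", "mean_mse",
                                             "median_iterations")],
                              -"sigma", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$sigma, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "kernel bandwidth σ", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-segment decoding errors by decoder
#'
#' @param report an `experiment_report` with a `per_segment` table.
#' @return a ggplot.
#' @export
plot_segment_errors <- function(report) {
  stopifnot(inherits(report, "experiment_report"), !is.null(report$per_segment))
  ggplot2::ggplot(report$per_segment,
                  ggplot2::aes(.data$decoder, .data$mse)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "2D-MSE",
                  title = paste0("Per-segment decoding error (",
                                 report$condition, ")")) +
    ggplot2::theme_minimal()
}
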