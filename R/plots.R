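#' Plot an interval distribution
#'
#' @param object An [interval_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.interval_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$interval, y = .data$prob)) +
    ggplot2::geom_col(width = 0.9, fill = "grey35") +
    ggplot2::labs(x = "interval between pulses (min)", y = "probability") +
    ggplot2::theme_minimal()
}

#' Histogram of single-cell bitrates with the transmitting threshold
#'
#' @param object A `bitrate_report` from [estimate_bitrate()].
#' @param binwidth Histogram bin width in bit/h.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bitrate_report <- function(object, binwidth = 1, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$cells, ggplot2::aes(x = .data$b)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey55",
                            color = "white") +
    ggplot2::geom_vline(xintercept = object$thresholds$threshold,
                        color = "blue", linetype = 2) +
    ggplot2::geom_vline(xintercept = g$bitrate, color = "orange") +
    ggplot2::labs(x = "single-cell bitrate (bit/h)", y = "cells") +
    ggplot2::theme_minimal()
}

#' Initial vs optimized interval distribution
#'
#' @param object An `optimized_protocol` from [optimize_protocol()].
#' @param init Optional initial [interval_distribution()] overlaid as a
#'   line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.optimized_protocol <- function(object, init = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(x = .data$interval, y = .data$prob)) +
    ggplot2::geom_col(width = 0.9, fill = "steelblue") +
    ggplot2::labs(x = "interval between pulses (min)", y = "probability") +
    ggplot2::theme_minimal()
  if (!is.null(init)) {
    p <- p + ggplot2::geom_step(data = tibble::as_tibble(init),
                                color = "black")
  }
  p
}

#' Tile map of mean logit updates by (interval, last)
#'
#' @param update_table A table from [mean_logit_update()].
#' @return A ggplot.
#' @export
plot_update_table <- function(update_table) {
  ggplot2::ggplot(update_table,
                  ggplot2::aes(x = .data$last, y = .data$interval,
                               fill = .data$mean_u)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkred", mid = "white",
                                  high = "darkblue", midpoint = 0,
                                  name = "mean u") +
    ggplot2::labs(x = "minutes since previous pulse",
                  y = "interval length (min)") +
    ggplot2::theme_minimal()
}

#' Neighbor transmission probability curves
#'
#' @param nb A table from [neighbor_transmission_probability()].
#' @return A ggplot.
#' @export
plot_neighbor_curves <- function(nb) {
  ggplot2::ggplot(nb, ggplot2::aes(x = .data$k, y = .data$prob,
                                   linetype = .data$anchor)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "neighbor rank k",
                  y = "P(kth neighbor transmits)") +
    ggplot2::theme_minimal()
}
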