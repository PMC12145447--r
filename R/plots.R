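#' Plot a positive-expression signal with detected smiles
#'
#' Line plot of the filtered score over time, with the detection threshold
#' as a dotted line, smile intervals shaded, and onset/offset frames marked.
#'
#' @param sig An `expression_signal` tibble.
#' @param track Optional smile-track tibble to overlay.
#' @param threshold Optional threshold to draw; defaults to the track's
#'   `threshold` attribute if present.
#' @return A ggplot object.
#' @export
plot_expression_signal <- function(sig, track = NULL, threshold = NULL) {
  fs <- sampling_rate(sig)
  p <- ggplot2::ggplot(sig, ggplot2::aes(x = .data$time_s, y = .data$score)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Positive-expression score (z)",
                  title = sig$participant_id[1]) +
    ggplot2::theme_minimal()
  threshold <- threshold %||% attr(track, "threshold", exact = TRUE)
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dotted")
  }
  if (!is.null(track) && nrow(track) > 0L) {
    shade <- tibble::tibble(xmin = (track$start_frame - 1) / fs,
                            xmax = (track$end_frame - 1) / fs)
    p <- p +
      ggplot2::geom_rect(data = shade,
                         ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                      ymin = -Inf, ymax = Inf),
                         inherit.aes = FALSE, alpha = 0.15, fill = "orchid") +
      ggplot2::geom_point(data = sig[sig$frame %in% track$start_frame, ],
                          colour = "blue", size = 1) +
      ggplot2::geom_point(data = sig[sig$frame %in% track$end_frame, ],
                          colour = "red", size = 1)
  }
  p
}

#' @rdname plot_expression_signal
#' @param object An `expression_signal`.
#' @param ... Passed to [plot_expression_signal()].
#' @export
autoplot.expression_signal <- function(object, ...) {
  plot_expression_signal(object, ...)
}

#' Plot shared smiles of a dyad
#'
#' Interval timeline for both participants, coloured by whether each smile
#' was shared with at least one partner smile.
#'
#' @param flagged Output of [flag_shared_smiles()].
#' @param fs Sampling rate, Hz.
#' @return A ggplot object.
#' @export
plot_shared_smiles <- function(flagged, fs = 30) {
  dat <- dplyr::mutate(flagged,
                       t0 = (.data$start_frame - 1) / fs,
                       t1 = (.data$end_frame - 1) / fs)
  ggplot2::ggplot(dat) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$t0, xend = .data$t1,
                                       y = .data$participant_id,
                                       yend = .data$participant_id,
                                       colour = .data$shared),
                          linewidth = 4) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "orchid", `FALSE` = "grey55"),
                                 name = "Shared") +
    ggplot2::labs(x = "Time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot group contrasts from a mixed-model comparison
#'
#' Contrast estimates with 95% confidence intervals, one row per pairwise
#' group contrast.
#'
#' @param object A `mimicry_group_fit` from [fit_group_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mimicry_group_fit <- function(object, ...) {
  ggplot2::ggplot(object$contrasts,
                  ggplot2::aes(x = .data$estimate, y = .data$contrast)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("Contrast estimate (%s)", object$outcome),
                  y = NULL,
                  title = "Tukey-adjusted pairwise group contrasts") +
    ggplot2::theme_minimal()
}
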