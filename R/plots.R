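# ggplot2 autoplot methods for the package's result types.

#' Plot a continuous signal
#'
#' @param object A [continuous_signal()].
#' @param from,to Optional time window (s) to restrict the plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.continuous_signal <- function(object, from = NULL, to = NULL, ...) {
  d <- as_tibble(object)
  if (!is.null(from)) d <- dplyr::filter(d, .data$time >= from)
  if (!is.null(to)) d <- dplyr::filter(d, .data$time <= to)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$voltage)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = expression(paste("voltage (", mu, "V)")))
}

#' Plot a power spectrum
#'
#' @param object A [compute_psd()] result.
#' @param log_power Plot power on a log10 axis (default TRUE).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrum_result <- function(object, log_power = TRUE, ...) {
  p <- ggplot2::ggplot(dplyr::filter(object, .data$frequency > 0),
                       ggplot2::aes(.data$frequency, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)",
                  y = expression(paste("power (", mu, V^2, "/Hz)")))
  if (log_power) p <- p + ggplot2::scale_y_log10() + ggplot2::scale_x_log10()
  p
}

#' Rose plot of achieved stimulation phases
#'
#' Histogram of the wrapped phase differences (achieved minus target) on a
#' polar axis, with the circular average marked.
#'
#' @param object A [evaluate_phase_accuracy()] result.
#' @param bins Number of angular bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phase_accuracy <- function(object, bins = 24, ...) {
  d <- tibble(phase_diff = object$events$phase_diff)
  ggplot2::ggplot(d, ggplot2::aes(.data$phase_diff)) +
    ggplot2::geom_histogram(breaks = seq(-pi, pi, length.out = bins + 1),
                            fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$circular_average,
                        colour = "red", linewidth = 1) +
    ggplot2::coord_polar(start = pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-pi, pi),
                                breaks = c(-pi / 2, 0, pi / 2, pi),
                                labels = c("-π/2", "0 (peak)", "π/2",
                                           "π (trough)")) +
    ggplot2::labs(x = NULL, y = "events")
}

#' Plot a coherence result
#'
#' Undefined (indeterminate) values are shown as gaps, never as zeros.
#'
#' @param object A [spike_field_coherence()] or [sfc_timecourse()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coherence_result <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$defined),
                  ggplot2::aes(.data$frequency, .data$coherence)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "frequency (Hz)", y = "spike-field coherence")
}

#' @rdname autoplot.coherence_result
#' @export
autoplot.coherence_timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$coherence)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(data = dplyr::filter(object, !.data$defined),
                        ggplot2::aes(y = 0), shape = 4, colour = "red") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (s)", y = "spike-field coherence",
                  caption = "red crosses: indeterminate windows (no spikes)")
}

#' Plot per-condition normalized values of an epoch comparison
#'
#' @param object A [compare_epochs()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.epoch_comparison <- function(object, ...) {
  ggplot2::ggplot(object$normalized,
                  ggplot2::aes(.data$condition, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL,
                  y = if (is.null(object$baseline)) "value"
                      else paste0("value / ", object$baseline))
}
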