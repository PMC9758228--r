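# broom-style tidiers for the package's result objects.

#' Tidy a phase-accuracy result
#'
#' @param x A [evaluate_phase_accuracy()] result.
#' @param ... Unused.
#' @return `tidy()`: one row per event with achieved phase and wrapped
#'   difference. `glance()`: one row with the circular summary.
#' @export
tidy.phase_accuracy <- function(x, ...) as_tibble(x$events)

#' @rdname tidy.phase_accuracy
#' @export
glance.phase_accuracy <- function(x, ...) {
  tibble(n_events = x$n_events,
         circular_average = x$circular_average,
         q1 = x$dispersion_interval[["q1"]],
         q3 = x$dispersion_interval[["q3"]],
         resultant_length = x$resultant_length,
         band_hz = x$band$center_frequency)
}

#' Tidy an epoch comparison
#'
#' @param x A [compare_epochs()] result.
#' @param ... Unused.
#' @return `tidy()`: per-condition n, median, and quartiles (normalized
#'   units when a baseline was used). `glance()`: one row with the test
#'   statistics.
#' @export
tidy.epoch_comparison <- function(x, ...) x$summary

#' @rdname tidy.epoch_comparison
#' @export
glance.epoch_comparison <- function(x, ...) {
  tibble(condition_1 = x$comparison[1], condition_2 = x$comparison[2],
         p_value = x$p_value, statistic = x$statistic,
         cohens_d = x$cohens_d, percent_change = x$percent_change)
}
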