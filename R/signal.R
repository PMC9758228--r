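#' Uniformly sampled continuous signal
#'
#' Container for a single-channel voltage trace: the substrate for phase
#' estimation. Samples are in microvolts (or any consistent unit), taken at
#' a fixed `sampling_rate` starting at `start_time`.
#'
#' @param samples Numeric vector of finite sample values.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample in seconds.
#' @return An object of class `continuous_signal`: a list with elements
#'   `samples`, `sampling_rate`, `start_time`.
#' @examples
#' t <- seq(0, 1, by = 1 / 1000)
#' sig <- continuous_signal(cos(2 * pi * 4 * t), 1000)
#' sig
#' @export
continuous_signal <- function(samples, sampling_rate, start_time = 0) {
  if (!is.numeric(samples) || length(samples) == 0)
    abort("`samples` must be a non-empty numeric vector", class = "phasestim_data_error")
  if (any(!is.finite(samples)))
    abort("`samples` must be finite", class = "phasestim_data_error")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0)
    abort("`sampling_rate` must be a single positive number", class = "phasestim_config_error")
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate),
         start_time = as.numeric(start_time)),
    class = "continuous_signal"
  )
}

#' @export
print.continuous_signal <- function(x, ...) {
  cat(sprintf("<continuous_signal> %d samples @ %g Hz, t = [%.6g, %.6g] s\n",
              length(x$samples), x$sampling_rate, x$start_time,
              x$start_time + (length(x$samples) - 1) / x$sampling_rate))
  invisible(x)
}

#' @export
length.continuous_signal <- function(x) length(x$samples)

#' Sample times of a continuous signal
#' @param signal A [continuous_signal()].
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(signal) {
  stopifnot(inherits(signal, "continuous_signal"))
  signal$start_time + (seq_along(signal$samples) - 1) / signal$sampling_rate
}

#' @export
as_tibble.continuous_signal <- function(x, ...) {
  tibble(time = signal_times(x), voltage = x$samples)
}

#' Extract a time slice of a signal
#'
#' @param signal A [continuous_signal()].
#' @param from,to Slice boundaries in seconds (inclusive of the samples that
#'   fall inside).
#' @return A [continuous_signal()] whose `start_time` is the time of its
#'   first retained sample.
#' @export
signal_window <- function(signal, from, to) {
  stopifnot(inherits(signal, "continuous_signal"))
  if (to <= from) abort("`to` must exceed `from`", class = "phasestim_config_error")
  tms <- signal_times(signal)
  keep <- which(tms >= from - 1e-12 & tms <= to + 1e-12)
  if (length(keep) == 0) abort("window contains no samples", class = "phasestim_data_error")
  continuous_signal(signal$samples[keep], signal$sampling_rate, tms[keep[1]])
}

# nearest sample index for a time point (1-based); clamps to support
.signal_index <- function(signal, time) {
  i <- round((time - signal$start_time) * signal$sampling_rate) + 1
  pmin(pmax(i, 1L), length(signal$samples))
}

# average-bin resample to a lower rate whose ratio divides evenly;
# falls back to linear interpolation otherwise
.resample_signal <- function(signal, new_rate) {
  if (abs(signal$sampling_rate - new_rate) < 1e-9) return(signal)
  ratio <- signal$sampling_rate / new_rate
  n <- length(signal$samples)
  if (abs(ratio - round(ratio)) < 1e-9 && ratio >= 1) {
    r <- as.integer(round(ratio))
    m <- floor(n / r)
    x <- matrix(signal$samples[seq_len(m * r)], nrow = r)
    continuous_signal(colMeans(x), new_rate,
                      signal$start_time + (r - 1) / (2 * signal$sampling_rate))
  } else {
    tms <- signal_times(signal)
    new_t <- seq(tms[1], tms[n], by = 1 / new_rate)
    continuous_signal(stats::approx(tms, signal$samples, new_t)$y, new_rate, new_t[1])
  }
}
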