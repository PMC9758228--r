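# Spike-field coherence: Welch-style magnitude-squared coherence between a
# binned spike train and the LFP, with explicit handling of indeterminate
# windows (no spikes), which are flagged rather than silently zeroed.

.bin_spikes <- function(spike_times, t0, t1, bin_s = 0.001) {
  edges <- seq(t0, t1, by = bin_s)
  counts <- tabulate(findInterval(spike_times, edges,
                                  rightmost.closed = FALSE, left.open = FALSE),
                     nbins = length(edges) - 1)
  list(counts = counts, rate = 1 / bin_s,
       centers = edges[-length(edges)] + bin_s / 2)
}

#' Spike-field coherence
#'
#' Magnitude-squared coherence between the 1-ms-binned, mean-subtracted
#' spike train and the LFP (resampled to the bin rate), estimated
#' Welch-style across non-overlapping windows of `window_s` seconds with
#' Hann tapering:
#' `C(f) = |sum_w Sxy|^2 / (sum_w Sxx * sum_w Syy)`.
#' Windows containing no spikes carry no phase information and are
#' excluded; if fewer than two windows remain the value is flagged
#' undefined (`defined = FALSE`, `coherence = NA`) -- indeterminate, never
#' silently zero.
#'
#' @param spikes A [spike_train()] (or numeric spike times).
#' @param lfp A [continuous_signal()] overlapping the spikes.
#' @param frequencies Frequencies (Hz) at which to report coherence
#'   (nearest FFT bin of the window length).
#' @param window_s Window length in seconds; must be >= `2 / min(frequencies)`.
#' @return A tibble of class `coherence_result`: `frequency`, `coherence`
#'   (in `[0, 1]` where defined, NA otherwise), `defined`, `n_windows`
#'   (windows retained).
#' @export
spike_field_coherence <- function(spikes, lfp, frequencies = c(4, 20),
                                  window_s = 5) {
  stopifnot(inherits(lfp, "continuous_signal"))
  if (is.numeric(spikes)) spikes <- spike_train(spikes)
  if (any(frequencies <= 0)) abort("`frequencies` must be > 0", class = "phasestim_config_error")
  if (window_s < 2 / min(frequencies))
    abort("`window_s` must cover at least two cycles of the lowest frequency",
          class = "phasestim_config_error")
  empty <- nrow(spikes) == 0
  if (empty) warn("empty spike train: all coherence values undefined")

  bin_s <- 0.001
  lfp_b <- .resample_signal(lfp, 1 / bin_s)
  tms <- signal_times(lfp_b)
  t0 <- tms[1]; t1 <- tms[length(tms)]
  bs <- .bin_spikes(spikes$spike_time[spikes$spike_time >= t0 &
                                        spikes$spike_time <= t1], t0, t1, bin_s)
  m <- min(length(bs$counts), length(lfp_b$samples))
  x <- bs$counts[seq_len(m)]
  y <- lfp_b$samples[seq_len(m)]
  nwin <- round(window_s / bin_s)
  n_windows <- floor(m / nwin)
  if (!empty && n_windows < 2)
    abort("signal shorter than two coherence windows", class = "phasestim_data_error")

  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))
  fgrid <- (seq_len(nwin) - 1) / (nwin * bin_s)
  bins <- vapply(frequencies, function(f) which.min(abs(fgrid - f)), 1L)
  sxy <- complex(length(bins)); sxx <- numeric(length(bins)); syy <- numeric(length(bins))
  used <- 0L
  for (k in seq_len(n_windows)) {
    i <- ((k - 1) * nwin + 1):(k * nwin)
    if (sum(x[i]) == 0) next                 # indeterminate window
    X <- fft((x[i] - mean(x[i])) * w)[bins]
    Y <- fft((y[i] - mean(y[i])) * w)[bins]
    sxy <- sxy + X * Conj(Y)
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    used <- used + 1L
  }
  if (used >= 2) {
    coh <- Mod(sxy)^2 / (sxx * syy)
    coh[!is.finite(coh)] <- NA_real_
    defined <- is.finite(coh)
  } else {
    coh <- rep(NA_real_, length(bins))
    defined <- rep(FALSE, length(bins))
  }
  out <- tibble(frequency = frequencies, coherence = coh,
                defined = defined, n_windows = used)
  class(out) <- c("coherence_result", class(out))
  out
}

#' Time-resolved spike-field coherence
#'
#' One coherence value per sliding window, estimated from `n_sub`
#' subsegments within each window. Windows without spikes yield NA
#' (indeterminate), mirroring how the time-resolved measure behaves on
#' real recordings when a unit falls silent.
#'
#' @param spikes,lfp As in [spike_field_coherence()].
#' @param frequency Single frequency of interest (Hz).
#' @param window_s Window length in seconds.
#' @param n_sub Subsegments per window used for the Welch average
#'   (default 4); each must cover two cycles of `frequency`.
#' @return A tibble with `time` (window center), `coherence`, `defined`.
#' @export
sfc_timecourse <- function(spikes, lfp, frequency = 4, window_s = 10,
                           n_sub = 4) {
  if (is.numeric(spikes)) spikes <- spike_train(spikes)
  sub_s <- window_s / n_sub
  if (sub_s < 2 / frequency)
    abort("`window_s / n_sub` must cover two cycles of `frequency`",
          class = "phasestim_config_error")
  tms <- signal_times(lfp)
  starts <- seq(tms[1], tms[length(tms)] - window_s, by = window_s)
  res <- purrr::map_dfr(starts, function(s) {
    seg <- signal_window(lfp, s, s + window_s)
    sp <- spikes$spike_time[spikes$spike_time >= s & spikes$spike_time < s + window_s]
    if (length(sp) == 0)
      return(tibble(time = s + window_s / 2, coherence = NA_real_, defined = FALSE))
    co <- tryCatch(
      spike_field_coherence(spike_train(sp), seg, frequencies = frequency,
                            window_s = sub_s),
      phasestim_data_error = function(e) NULL)
    if (is.null(co) || !co$defined[1])
      tibble(time = s + window_s / 2, coherence = NA_real_, defined = FALSE)
    else tibble(time = s + window_s / 2, coherence = co$coherence[1], defined = TRUE)
  })
  class(res) <- c("coherence_timecourse", class(res))
  res
}
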