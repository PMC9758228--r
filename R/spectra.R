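# Welch power spectra and band power.

#' Welch power spectral density
#'
#' Averaged periodogram over Hann-tapered, demeaned segments with
#' fractional overlap. One-sided density scaled so that the integral of
#' `power` over frequency approximates the signal variance (Parseval).
#'
#' @param signal A [continuous_signal()] at least one segment long.
#' @param segment_s Segment length in seconds.
#' @param overlap_fraction Fractional overlap between segments in `[0, 1)`.
#' @return A tibble of class `spectrum_result` with columns `frequency`
#'   (Hz, 0..Nyquist) and `power` (units^2/Hz).
#' @export
compute_psd <- function(signal, segment_s = 2, overlap_fraction = 0.5) {
  stopifnot(inherits(signal, "continuous_signal"))
  fs <- signal$sampling_rate
  nseg <- round(segment_s * fs)
  n <- length(signal$samples)
  if (nseg > n) abort("segment longer than signal", class = "phasestim_data_error")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    abort("`overlap_fraction` must be in [0, 1)", class = "phasestim_config_error")
  step <- max(1, round(nseg * (1 - overlap_fraction)))
  starts <- seq(1, n - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))   # Hann
  U <- sum(w^2)
  nf <- floor(nseg / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- signal$samples[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(fft(seg))^2 / (fs * U)
    acc <- acc + P[seq_len(nf)]
  }
  pw <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when present)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[nf] <- 1
  out <- tibble(frequency = (seq_len(nf) - 1) * fs / nseg, power = pw * dbl)
  class(out) <- c("spectrum_result", class(out))
  attr(out, "segment_s") <- segment_s
  out
}

#' Integrated band power
#'
#' Trapezoidal integral of a power spectral density over a frequency band.
#'
#' @param spectrum A [compute_psd()] result (or any tibble with
#'   `frequency` and `power`).
#' @param band Length-2 numeric `(low, high)` in Hz, inside the spectrum's
#'   frequency grid.
#' @return Band power in units^2.
#' @export
band_power <- function(spectrum, band) {
  if (!all(c("frequency", "power") %in% names(spectrum)))
    abort("`spectrum` needs `frequency` and `power` columns", class = "phasestim_data_error")
  if (length(band) != 2 || band[2] <= band[1])
    abort("`band` must be (low, high) with high > low", class = "phasestim_config_error")
  f <- spectrum$frequency
  if (band[1] < f[1] - 1e-9 || band[2] > f[length(f)] + 1e-9)
    abort("`band` outside the spectrum's frequency grid", class = "phasestim_data_error")
  keep <- f >= band[1] & f <= band[2]
  if (sum(keep) < 2) abort("`band` spans fewer than two frequency bins",
                           class = "phasestim_data_error")
  pracma::trapz(f[keep], spectrum$power[keep])
}
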