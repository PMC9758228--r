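# Complex Morlet phase/frequency/amplitude estimation and the acausal
# analytic-signal oracle used for offline scoring.

#' Complex Morlet wavelet kernel
#'
#' A Gaussian-windowed complex exponential with temporal SD
#' `n_cycles / (2 * pi * center_frequency)` and total duration
#' `n_cycles / center_frequency` (about +/- 3 SD). The discrete mean is
#' subtracted (admissibility correction) and the kernel is L2-normalized.
#' Its inner product with a signal window yields the band amplitude
#' (after the stored `amp_scale` calibration) and phase at the kernel
#' center under the cosine convention (0 = peak).
#'
#' @param band A [band_spec()].
#' @param sampling_rate Sampling rate in Hz; must be >= 4x the band center.
#' @return A list of class `morlet_kernel`: `values` (complex, odd length),
#'   `n_half` (samples each side of center), `duration_s`, `amp_scale`
#'   (coefficient magnitude produced by a unit-amplitude sinusoid at the
#'   center frequency), `band`, `sampling_rate`.
#' @export
morlet_kernel <- function(band, sampling_rate) {
  stopifnot(inherits(band, "band_spec"))
  f0 <- band$center_frequency
  if (sampling_rate < 4 * f0)
    abort("`sampling_rate` must be >= 4x the band center frequency",
          class = "phasestim_config_error")
  sd_t <- band$n_cycles / (2 * pi * f0)
  n_half <- round(band$n_cycles / (2 * f0) * sampling_rate)
  t <- (-n_half:n_half) / sampling_rate
  k <- exp(-t^2 / (2 * sd_t^2)) * exp(1i * 2 * pi * f0 * t)
  k <- k - mean(k)                      # exact zero mean (admissibility)
  k <- k / sqrt(sum(Mod(k)^2))          # unit L2 norm
  amp_scale <- Mod(sum(cos(2 * pi * f0 * t) * Conj(k)))
  structure(list(values = k, n_half = n_half,
                 duration_s = (2 * n_half) / sampling_rate,
                 amp_scale = amp_scale, band = band,
                 sampling_rate = sampling_rate),
            class = "morlet_kernel")
}

#' Continuous wavelet transform of a signal at one band
#'
#' Cross-correlates the signal with the conjugate Morlet kernel by FFT
#' convolution. Coefficient `t` uses samples `t - n_half .. t + n_half`,
#' so a causal system knows coefficient `t` once sample `t + n_half` has
#' arrived: the kernel half-length is the estimation (group) lag, which the
#' closed-loop controller folds into its prediction horizon.
#'
#' @param signal A [continuous_signal()].
#' @param band A [band_spec()].
#' @return A list of class `wavelet_series`: `coef` (complex, NA outside
#'   the valid center range), `valid` (index range), `kernel`, plus the
#'   signal's rate/start time. Phase = `Arg(coef)`; amplitude =
#'   `Mod(coef) / kernel$amp_scale`.
#' @export
wavelet_transform <- function(signal, band) {
  stopifnot(inherits(signal, "continuous_signal"))
  kern <- morlet_kernel(band, signal$sampling_rate)
  x <- signal$samples
  n <- length(x)
  L <- 2 * kern$n_half + 1
  if (n < L)
    abort("signal shorter than the wavelet kernel", class = "phasestim_data_error")
  h <- Conj(rev(kern$values))
  N <- nextn(n + L - 1, c(2, 3, 5))
  conv <- fft(fft(c(x, numeric(N - n))) * fft(c(h, numeric(N - L))),
              inverse = TRUE) / N
  # full convolution index t + n_half holds the centered coefficient at t
  coef <- conv[seq_len(n) + kern$n_half]
  valid <- c(kern$n_half + 1L, n - kern$n_half)
  coef[seq_len(valid[1] - 1)] <- NA
  if (valid[2] < n) coef[(valid[2] + 1L):n] <- NA
  structure(list(coef = coef, valid = valid, kernel = kern,
                 sampling_rate = signal$sampling_rate,
                 start_time = signal$start_time),
            class = "wavelet_series")
}

#' @export
as_tibble.wavelet_series <- function(x, ...) {
  n <- length(x$coef)
  tibble(time = x$start_time + (seq_len(n) - 1) / x$sampling_rate,
         phase = Arg(x$coef),
         amplitude = Mod(x$coef) / x$kernel$amp_scale)
}

# phase-slope instantaneous frequency at given coefficient centers.
# Least-squares slope of unwrapped phase over K points spanning `span_s`
# seconds back from each center; clamped to the band passband.
.wavelet_frequency <- function(ws, centers, span_s = 0.025, K = 6L) {
  fs <- ws$sampling_rate
  step <- max(1L, round(span_s / (K - 1) * fs))
  offs <- (-(K - 1L):0L) * step
  idx <- outer(centers, offs, `+`)
  if (any(idx < 1)) abort("not enough history for frequency estimation",
                          class = "phasestim_data_error")
  ph <- matrix(Arg(ws$coef[idx]), nrow = length(centers))
  dph <- wrap_phase(ph[, -1, drop = FALSE] - ph[, -K, drop = FALSE])
  # unwrap: y_j = cumulative sum of wrapped increments (y_1 = 0)
  Tm <- matrix(0, K - 1, K - 1)
  Tm[upper.tri(Tm, diag = TRUE)] <- 1
  y <- cbind(0, dph %*% Tm)
  xj <- seq_len(K)
  cx <- (xj - mean(xj)) / sum((xj - mean(xj))^2)
  slope <- as.numeric(y %*% cx)              # rad per step
  freq <- slope / (2 * pi * step / fs)
  pb <- ws$kernel$band$passband
  pmin(pmax(freq, pb[1]), pb[2])
}

#' Estimate instantaneous phase, frequency, and amplitude causally
#'
#' Takes a buffered window of signal (the most recent data available to a
#' real-time system) and returns the band estimate at the newest time point
#' the centered kernel can cover: `window end - kernel half-length`. The
#' frequency is the least-squares slope of the unwrapped wavelet phase over
#' the trailing 25 ms of coefficients, clamped to the band passband. A
#' window whose band amplitude is numerically zero yields an
#' undefined-phase flag rather than a garbage angle.
#'
#' @param window A [continuous_signal()] at least as long as the kernel
#'   plus 25 ms of frequency-fit history.
#' @param band A [band_spec()].
#' @return One-row tibble of class `phase_estimate`: `time` (s), `phase`
#'   (radians, (-pi, pi]), `frequency` (Hz), `amplitude` (signal units),
#'   `undefined` (logical).
#' @export
estimate_phase <- function(window, band) {
  ws <- wavelet_transform(window, band)
  center <- ws$valid[2]
  span <- max(1L, round(0.025 * ws$sampling_rate))
  if (center - span < ws$valid[1])
    abort("window too short: need kernel length plus 25 ms of history",
          class = "phasestim_data_error")
  co <- ws$coef[center]
  amp <- Mod(co) / ws$kernel$amp_scale
  undef <- amp < 1e-12
  out <- tibble(
    time = ws$start_time + (center - 1) / ws$sampling_rate,
    phase = if (undef) NA_real_ else Arg(co),
    frequency = if (undef) band$center_frequency
                else .wavelet_frequency(ws, center),
    amplitude = amp,
    undefined = undef
  )
  class(out) <- c("phase_estimate", class(out))
  out
}

#' Predict phase at a future time by linear extrapolation
#'
#' Advances the estimated phase at the estimated instantaneous frequency:
#' `wrap(phase + 2 * pi * frequency * horizon)`. This is how a closed-loop
#' controller compensates its latency budget: predict the phase at the
#' moment the pulse will actually arrive.
#'
#' @param estimate A [estimate_phase()] result, or any list/one-row data
#'   frame with `phase` and `frequency` fields.
#' @param horizon Look-ahead in seconds (>= 0).
#' @return Predicted phase in radians, in (-pi, pi].
#' @examples
#' predict_phase(list(phase = 0, frequency = 4), 0.05)    # 0.4 * pi
#' predict_phase(list(phase = 0, frequency = 20), 0.05)   # 0: one full cycle
#' @export
predict_phase <- function(estimate, horizon) {
  if (any(horizon < 0)) abort("`horizon` must be >= 0", class = "phasestim_config_error")
  ph <- estimate$phase
  fr <- estimate$frequency
  if (is.null(ph) || is.null(fr))
    abort("`estimate` needs `phase` and `frequency`", class = "phasestim_data_error")
  wrap_phase(ph + 2 * pi * fr * horizon)
}

#' Acausal ground-truth phase: zero-phase band-pass + analytic signal
#'
#' The offline scoring oracle. The signal is band-passed with a zero-phase
#' frequency-domain filter (brick wall with raised-cosine transitions, so
#' no group delay and no filter ringing at very low normalized
#' frequencies), then the analytic signal is formed and its argument taken.
#' Unlike the causal wavelet estimate this uses future samples, which is
#' exactly why it serves as ground truth.
#'
#' @param signal A [continuous_signal()].
#' @param passband Length-2 numeric `(low, high)` in Hz.
#' @param transition_frac Width of each raised-cosine transition as a
#'   fraction of the band edge frequency (default 0.25).
#' @return A tibble with columns `time`, `phase`, `amplitude`.
#' @export
acausal_phase <- function(signal, passband, transition_frac = 0.25) {
  stopifnot(inherits(signal, "continuous_signal"))
  if (length(passband) != 2 || passband[1] <= 0 || passband[2] <= passband[1])
    abort("`passband` must be (low, high), 0 < low < high", class = "phasestim_config_error")
  x <- signal$samples - mean(signal$samples)
  n <- length(x)
  fs <- signal$sampling_rate
  f <- (seq_len(n) - 1) * fs / n
  f2 <- pmin(f, fs - f)                 # mirrored two-sided frequency axis
  lo <- passband[1]; hi <- passband[2]
  tw_lo <- lo * transition_frac; tw_hi <- hi * transition_frac
  g <- numeric(n)
  g[f2 >= lo & f2 <= hi] <- 1
  ramp_up <- f2 > lo - tw_lo & f2 < lo
  g[ramp_up] <- 0.5 * (1 - cos(pi * (f2[ramp_up] - (lo - tw_lo)) / tw_lo))
  ramp_dn <- f2 > hi & f2 < hi + tw_hi
  g[ramp_dn] <- 0.5 * (1 + cos(pi * (f2[ramp_dn] - hi) / tw_hi))
  xb <- Re(fft(fft(x) * g, inverse = TRUE)) / n
  # analytic signal: zero negative frequencies, double positive ones
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else h[2:((n + 1) / 2)] <- 2
  a <- fft(fft(xb) * h, inverse = TRUE) / n
  tibble(time = signal_times(signal), phase = Arg(a), amplitude = Mod(a))
}
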