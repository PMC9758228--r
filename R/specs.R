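#' Oscillator specification for the synthetic LFP generator
#'
#' Describes one band-limited rhythm: a sinusoid whose instantaneous
#' frequency follows a slow, reflected random walk around
#' `center_frequency` and whose amplitude is modulated by a slow
#' multiplicative process. Defaults mirror the striatal targets this
#' package models: a ~4 Hz low-frequency rhythm and a ~20 Hz beta rhythm.
#'
#' @param center_frequency Center frequency in Hz (> 0).
#' @param amplitude Oscillation amplitude in signal units (>= 0).
#' @param frequency_jitter_sd Diffusion of the instantaneous-frequency
#'   random walk, expressed as the SD (Hz) accumulated over one second.
#'   0 gives a constant-frequency sinusoid.
#' @param amplitude_jitter_sd Fractional SD of the slow amplitude
#'   modulation (0 disables it).
#' @param reflect_halfwidth Half-width (Hz) of the band within which the
#'   frequency walk is reflected; default `min(center_frequency / 2, 4)`,
#'   keeping a 4 Hz oscillator within 2--6 Hz and a 20 Hz oscillator
#'   within 16--24 Hz.
#' @param phase0 Initial phase in radians (0 = start at a peak).
#' @return A validated list of class `oscillator_spec`.
#' @export
oscillator_spec <- function(center_frequency, amplitude = 1,
                            frequency_jitter_sd = 0, amplitude_jitter_sd = 0,
                            reflect_halfwidth = min(center_frequency / 2, 4),
                            phase0 = 0) {
  if (center_frequency <= 0) abort("`center_frequency` must be > 0", class = "phasestim_config_error")
  if (amplitude < 0) abort("`amplitude` must be >= 0", class = "phasestim_config_error")
  if (frequency_jitter_sd < 0 || amplitude_jitter_sd < 0)
    abort("jitter SDs must be >= 0", class = "phasestim_config_error")
  if (reflect_halfwidth <= 0 || reflect_halfwidth >= center_frequency)
    abort("`reflect_halfwidth` must be in (0, center_frequency)", class = "phasestim_config_error")
  structure(list(center_frequency = center_frequency, amplitude = amplitude,
                 frequency_jitter_sd = frequency_jitter_sd,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 reflect_halfwidth = reflect_halfwidth,
                 phase0 = wrap_phase(phase0)),
            class = "oscillator_spec")
}

#' Background-noise specification (1/f spectrum)
#'
#' Gaussian noise with power spectral density proportional to
#' `1/f^exponent`, scaled so its broadband standard deviation equals
#' `scale` (signal units). `exponent = 0` gives white noise.
#'
#' @param exponent Spectral exponent, in `[0, 3]`.
#' @param scale Broadband SD of the noise in signal units (>= 0; 0 disables).
#' @return A validated list of class `noise_spec`.
#' @export
noise_spec <- function(exponent = 1, scale = 0.5) {
  if (exponent < 0 || exponent > 3)
    abort("`exponent` must be in [0, 3]", class = "phasestim_config_error")
  if (scale < 0) abort("`scale` must be >= 0", class = "phasestim_config_error")
  structure(list(exponent = exponent, scale = scale), class = "noise_spec")
}

#' Spike-generator specification
#'
#' Phase-locked spiking is modeled as an inhomogeneous Poisson process with
#' von Mises intensity
#' `base_rate * exp(kappa * cos(phase - preferred_phase)) / I0(kappa)`,
#' whose time-average over a full cycle equals `base_rate`. Stimulation
#' pulses additionally evoke a spike with probability `evoked_probability`
#' at `evoked_latency_ms` after delivery, reflecting the short-latency
#' opto-evoked responses of directly stimulated units.
#'
#' @param base_rate Mean firing rate in spikes/s (>= 0).
#' @param locking_concentration von Mises concentration kappa (>= 0;
#'   0 = no phase preference).
#' @param preferred_phase Preferred phase in radians, (-pi, pi].
#' @param evoked_probability Probability a pulse evokes one extra spike.
#' @param evoked_latency_ms Latency of evoked spikes after pulse delivery,
#'   in milliseconds (default 3, under the 5 ms bound typical of direct
#'   opsin activation).
#' @return A validated list of class `spike_spec`.
#' @export
spike_spec <- function(base_rate = 5, locking_concentration = 0,
                       preferred_phase = 0, evoked_probability = 0,
                       evoked_latency_ms = 3) {
  if (base_rate < 0) abort("`base_rate` must be >= 0", class = "phasestim_config_error")
  if (locking_concentration < 0) abort("kappa must be >= 0", class = "phasestim_config_error")
  if (evoked_probability < 0 || evoked_probability > 1)
    abort("`evoked_probability` must be in [0, 1]", class = "phasestim_config_error")
  if (evoked_latency_ms < 0)
    abort("`evoked_latency_ms` must be >= 0", class = "phasestim_config_error")
  structure(list(base_rate = base_rate,
                 locking_concentration = locking_concentration,
                 preferred_phase = wrap_phase(preferred_phase),
                 evoked_probability = evoked_probability,
                 evoked_latency_ms = evoked_latency_ms),
            class = "spike_spec")
}

#' Head-motion specification
#'
#' Head velocity is an Ornstein--Uhlenbeck process in each of the three
#' coordinates with correlation time `smoothness`; its stationary scale is
#' set per condition epoch so the expected speed equals
#' `baseline_speed * condition_speed_multipliers[[condition]]`.
#'
#' @param frame_rate Tracking frame rate in frames/s (default 120, the
#'   standard infrared motion-capture rate).
#' @param baseline_speed Expected speed (mm/s) in unlabeled time and in
#'   conditions with multiplier 1.
#' @param condition_speed_multipliers Named list/vector mapping condition
#'   labels to positive speed multipliers.
#' @param smoothness Velocity correlation time in seconds.
#' @return A validated list of class `motion_spec`.
#' @export
motion_spec <- function(frame_rate = 120, baseline_speed = 20,
                        condition_speed_multipliers = list(no_stim = 1),
                        smoothness = 0.5) {
  if (frame_rate <= 0) abort("`frame_rate` must be > 0", class = "phasestim_config_error")
  if (baseline_speed < 0) abort("`baseline_speed` must be >= 0", class = "phasestim_config_error")
  m <- unlist(condition_speed_multipliers)
  if (length(m) && any(m <= 0)) abort("multipliers must be > 0", class = "phasestim_config_error")
  if (smoothness <= 0) abort("`smoothness` must be > 0", class = "phasestim_config_error")
  structure(list(frame_rate = frame_rate, baseline_speed = baseline_speed,
                 condition_speed_multipliers = as.list(m),
                 smoothness = smoothness),
            class = "motion_spec")
}

#' Frequency-band specification for phase estimation
#'
#' Defines the analysis band: the Morlet center frequency and width for
#' causal estimation, and the pass band used by the acausal zero-phase
#' oracle. The defaults follow common practice for these two targets: a
#' 4-cycle wavelet at 4 Hz (shorter causal lag at the cost of frequency
#' selectivity) and a 7-cycle wavelet at 20 Hz.
#'
#' @param center_frequency Band center in Hz.
#' @param n_cycles Morlet width in cycles (>= 3).
#' @param passband Length-2 numeric, `(low, high)` in Hz; must bracket
#'   `center_frequency`. Defaults: `(2, 8)` for centers below 10 Hz,
#'   `(16, 25)` at 20 Hz, else `center_frequency * c(0.8, 1.25)`.
#' @return A validated list of class `band_spec`.
#' @export
band_spec <- function(center_frequency, n_cycles = NULL, passband = NULL) {
  if (center_frequency <= 0) abort("`center_frequency` must be > 0", class = "phasestim_config_error")
  if (is.null(n_cycles)) n_cycles <- if (center_frequency < 10) 4 else 7
  if (n_cycles < 3) abort("`n_cycles` must be >= 3", class = "phasestim_config_error")
  if (is.null(passband)) {
    passband <- if (center_frequency < 10) c(2, 8)
    else if (abs(center_frequency - 20) < 1e-9) c(16, 25)
    else center_frequency * c(0.8, 1.25)
  }
  if (length(passband) != 2 || passband[1] <= 0 || passband[2] <= passband[1])
    abort("`passband` must be (low, high) with 0 < low < high", class = "phasestim_config_error")
  if (center_frequency < passband[1] || center_frequency > passband[2])
    abort("`passband` must contain `center_frequency`", class = "phasestim_config_error")
  structure(list(center_frequency = center_frequency, n_cycles = n_cycles,
                 passband = as.numeric(passband)),
            class = "band_spec")
}

#' Closed-loop latency model
#'
#' The five delays between a voltage sample existing at the electrode and
#' light arriving at the tissue: acquisition-hardware delay, input
#' buffering, phase computation, message transport, and actuator (laser)
#' rise time. Defaults are the measured component medians of a working
#' implementation of this architecture: acquisition < 0.1 ms (modeled as
#' 0), 10.00 ms buffer, 2.05 ms computation, 0.21 ms transport, and 0.74 ms
#' laser rise, totaling 13.00 ms.
#'
#' @param acquisition_ms,buffer_ms,compute_ms,transport_ms,actuator_rise_ms
#'   Non-negative delays in milliseconds.
#' @return A validated list of class `latency_model`.
#' @seealso [total_latency()]
#' @export
latency_model <- function(acquisition_ms = 0, buffer_ms = 10,
                          compute_ms = 2.05, transport_ms = 0.21,
                          actuator_rise_ms = 0.74) {
  v <- c(acquisition_ms, buffer_ms, compute_ms, transport_ms, actuator_rise_ms)
  if (any(v < 0)) abort("latency components must be >= 0", class = "phasestim_config_error")
  if (buffer_ms <= 0) abort("`buffer_ms` must be > 0", class = "phasestim_config_error")
  structure(list(acquisition_ms = acquisition_ms, buffer_ms = buffer_ms,
                 compute_ms = compute_ms, transport_ms = transport_ms,
                 actuator_rise_ms = actuator_rise_ms),
            class = "latency_model")
}

#' Stimulation policy
#'
#' When to fire: the controller predicts the band phase at the moment a
#' pulse commanded now would be delivered, and fires when that prediction
#' falls inside a window around `target_phase`, the estimated amplitude
#' clears `amplitude_gate`, and at least `refractory_s` has elapsed since
#' the previous delivery. With `target_phase = "random"` the phase test is
#' replaced by a Bernoulli draw whose per-hop probability matches the
#' expected one-pulse-per-cycle rate, giving a phase-random control
#' condition.
#'
#' @param band A [band_spec()].
#' @param target_phase Target phase in radians (0 = peak, pi = trough) or
#'   the string `"random"`.
#' @param phase_tolerance Maximum |predicted - target| allowed to fire, in
#'   radians, in (0, pi].
#' @param refractory_s Minimum interval between deliveries in seconds;
#'   default half the target period, bounding the pulse rate near the band
#'   frequency.
#' @param pulse_width_ms Light-pulse width in ms (default 5).
#' @param amplitude_gate Minimum estimated band amplitude required to fire
#'   (signal units; 0 disables gating).
#' @return A validated list of class `stim_policy`.
#' @export
stim_policy <- function(band, target_phase = 0, phase_tolerance = 0.3,
                        refractory_s = NULL, pulse_width_ms = 5,
                        amplitude_gate = 0) {
  stopifnot(inherits(band, "band_spec"))
  random <- identical(target_phase, "random")
  if (!random) {
    if (!is.numeric(target_phase) || length(target_phase) != 1)
      abort("`target_phase` must be a single angle or \"random\"", class = "phasestim_config_error")
    target_phase <- wrap_phase(target_phase)
  }
  if (phase_tolerance <= 0 || phase_tolerance > pi)
    abort("`phase_tolerance` must be in (0, pi]", class = "phasestim_config_error")
  if (pulse_width_ms <= 0) abort("`pulse_width_ms` must be > 0", class = "phasestim_config_error")
  if (is.null(refractory_s)) refractory_s <- 1 / (2 * band$center_frequency)
  if (refractory_s < pulse_width_ms / 1000)
    abort("`refractory_s` must be >= pulse width", class = "phasestim_config_error")
  if (amplitude_gate < 0) abort("`amplitude_gate` must be >= 0", class = "phasestim_config_error")
  structure(list(band = band, target_phase = target_phase, random = random,
                 phase_tolerance = phase_tolerance, refractory_s = refractory_s,
                 pulse_width_ms = pulse_width_ms, amplitude_gate = amplitude_gate),
            class = "stim_policy")
}

.epoch_conditions <- c("no_stim", "peak", "trough", "random")

#' Labeled condition epochs
#'
#' A set of non-overlapping time intervals, each labeled with a stimulation
#' condition (`no_stim`, `peak`, `trough`, or `random`), over which
#' analytics are aggregated. Conventionally 30-s epochs.
#'
#' @param start,end Epoch boundaries in seconds (`end > start`).
#' @param condition Character vector of condition labels.
#' @param block Optional replicate/block identifier per epoch (defaults to
#'   the running count of each condition), used as the pairing unit in
#'   condition contrasts.
#' @return A tibble of class `epoch_set` with columns `start`, `end`,
#'   `condition`, `block`.
#' @export
epoch_set <- function(start, end, condition, block = NULL) {
  if (length(start) != length(end) || length(start) != length(condition))
    abort("`start`, `end`, `condition` must have equal length", class = "phasestim_data_error")
  if (any(end <= start))
    abort("every epoch must have `end` > `start`", class = "phasestim_data_error")
  condition <- as.character(condition)
  bad <- setdiff(unique(condition), .epoch_conditions)
  if (length(bad))
    abort(paste0("unknown condition label(s): ", paste(bad, collapse = ", ")),
          class = "phasestim_data_error")
  ord <- order(start)
  if (length(start) > 1) {
    s <- start[ord]; e <- end[ord]
    ov <- which(s[-1] < e[-length(e)] - 1e-12)
    if (length(ov))
      abort(paste0("overlapping epochs at sorted rows: ",
                   paste(ov, ov + 1, sep = "-", collapse = ", ")),
            class = "phasestim_data_error")
  }
  if (is.null(block)) {
    block <- stats::ave(seq_along(condition[ord]), condition[ord], FUN = seq_along)
  } else {
    block <- block[ord]
  }
  out <- tibble(start = start[ord], end = end[ord],
                condition = condition[ord], block = as.integer(block))
  class(out) <- c("epoch_set", class(out))
  out
}
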