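# Synthetic inputs with the statistical structure the closed loop assumes:
# band-limited oscillators with slowly wandering frequency in 1/f noise,
# von Mises phase-locked spiking, pulse-evoked spikes, and smooth 3-D head
# trajectories. All generators are deterministic given `seed`.

# reflect a random walk into [lo, hi]
.reflect <- function(x, lo, hi) {
  period <- 2 * (hi - lo)
  y <- (x - lo) %% period
  lo + ifelse(y > (hi - lo), period - y, y)
}

#' Generate a synthetic local field potential
#'
#' Sums one sinusoid per oscillator whose instantaneous frequency follows a
#' reflected Gaussian random walk around its center (so the rhythm stays
#' inside its analysis band) over 1/f-shaped Gaussian background noise.
#' Ground-truth per-oscillator phase traces are returned alongside the
#' signal so downstream estimates can be scored exactly.
#'
#' @param oscillators A single [oscillator_spec()] or list of them (may be
#'   empty for pure noise).
#' @param noise A [noise_spec()].
#' @param duration Signal duration in seconds (> 0).
#' @param sampling_rate Sampling rate in Hz; must be at least 4x the
#'   fastest oscillator. Default 30000, the resolution of the acquisition
#'   hardware this package models; desk-scale analyses typically use 1000.
#' @param seed Integer seed; equal seeds give bit-identical output.
#' @return A [continuous_signal()] with an extra element `truth`: a tibble
#'   with column `time` and one `phase_<k>` / `frequency_<k>` pair per
#'   oscillator (radians, Hz).
#' @examples
#' sig <- generate_lfp(oscillator_spec(4), noise_spec(1, 0.5),
#'                     duration = 2, sampling_rate = 1000, seed = 1)
#' @export
generate_lfp <- function(oscillators, noise = noise_spec(),
                         duration, sampling_rate = 30000, seed = 1L) {
  if (inherits(oscillators, "oscillator_spec")) oscillators <- list(oscillators)
  stopifnot(all(vapply(oscillators, inherits, TRUE, "oscillator_spec")),
            inherits(noise, "noise_spec"))
  if (duration <= 0) abort("`duration` must be > 0", class = "phasestim_config_error")
  if (sampling_rate <= 0) abort("`sampling_rate` must be > 0", class = "phasestim_config_error")
  fmax <- if (length(oscillators)) max(vapply(oscillators, `[[`, 0, "center_frequency")) else 0
  if (length(oscillators) && sampling_rate < 4 * fmax)
    abort("`sampling_rate` must be >= 4x the fastest oscillator", class = "phasestim_config_error")

  n <- round(duration * sampling_rate)
  dt <- 1 / sampling_rate
  withr::with_seed(as.integer(seed), {
    x <- numeric(n)
    truth <- tibble(time = (seq_len(n) - 1) * dt)
    for (k in seq_along(oscillators)) {
      o <- oscillators[[k]]
      if (o$frequency_jitter_sd > 0) {
        walk <- cumsum(c(0, rnorm(n - 1, 0, o$frequency_jitter_sd * sqrt(dt))))
        f <- .reflect(o$center_frequency + walk,
                      o$center_frequency - o$reflect_halfwidth,
                      o$center_frequency + o$reflect_halfwidth)
      } else {
        f <- rep(o$center_frequency, n)
      }
      # phase[i] integrates frequency up to (not including) sample i, so
      # phase[1] is exactly phase0
      ph <- o$phase0 + 2 * pi * dt * c(0, cumsum(f[-n]))
      if (o$amplitude_jitter_sd > 0) {
        # slow (1 s correlation time) multiplicative amplitude modulation
        alpha <- exp(-dt)
        z <- stats::filter(rnorm(n, 0, sqrt(1 - alpha^2)), alpha,
                           method = "recursive")
        a <- pmax(0, o$amplitude * (1 + o$amplitude_jitter_sd * as.numeric(z)))
      } else {
        a <- rep(o$amplitude, n)
      }
      x <- x + a * cos(ph)
      truth[[paste0("phase_", k)]] <- wrap_phase(ph)
      truth[[paste0("frequency_", k)]] <- f
    }
    if (noise$scale > 0) x <- x + .pink_noise(n, sampling_rate, noise)
  })
  sig <- continuous_signal(x, sampling_rate, start_time = 0)
  sig$truth <- truth
  sig
}

# Gaussian noise with power ~ 1/f^exponent, broadband SD = scale.
# Shaped in the frequency domain; consumes RNG from the caller's stream.
.pink_noise <- function(n, sampling_rate, noise) {
  w <- rnorm(n)
  if (noise$exponent == 0) return(noise$scale * w)
  W <- fft(w)
  f <- (seq_len(n) - 1) * sampling_rate / n
  f <- pmin(f, sampling_rate - f)      # two-sided spectrum
  g <- ifelse(f > 0, f^(-noise$exponent / 2), 0)
  x <- Re(fft(W * g, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  noise$scale * x / s
}

#' Generate spikes phase-locked to an oscillation
#'
#' Inhomogeneous Poisson process with von Mises intensity
#' `base_rate * exp(kappa * cos(phase - mu)) / I0(kappa)`; the I0
#' normalization keeps the cycle-averaged rate at `base_rate` regardless
#' of the locking strength. Simulated by per-sample Bernoulli thinning on
#' the phase-trace grid with sub-bin jitter, so spike times are strictly
#' increasing.
#'
#' @param phase_trace A tibble with columns `time` (s, uniform grid) and
#'   `phase` (radians), e.g. the `truth` element of [generate_lfp()]
#'   renamed, or any phase series.
#' @param spec A [spike_spec()].
#' @param seed Integer seed.
#' @return A tibble of class `spike_train` with columns `spike_time` (s)
#'   and `unit_id`.
#' @export
generate_phase_locked_spikes <- function(phase_trace, spec, seed = 1L) {
  stopifnot(inherits(spec, "spike_spec"))
  if (!is.data.frame(phase_trace) || !all(c("time", "phase") %in% names(phase_trace)))
    abort("`phase_trace` needs `time` and `phase` columns", class = "phasestim_data_error")
  if (nrow(phase_trace) < 2)
    abort("`phase_trace` must not be empty", class = "phasestim_data_error")
  if (any(!is.finite(phase_trace$phase)))
    abort("`phase_trace` must be finite", class = "phasestim_data_error")
  tms <- phase_trace$time
  dt <- tms[2] - tms[1]
  if (spec$base_rate == 0) return(spike_train(numeric(0)))
  kap <- spec$locking_concentration
  lam <- spec$base_rate *
    exp(kap * cos(phase_trace$phase - spec$preferred_phase)) / besselI(kap, 0)
  p <- lam * dt
  if (max(p) > 0.5)
    warn("spike probability per bin exceeds 0.5; use a finer phase grid")
  withr::with_seed(as.integer(seed), {
    hit <- which(runif(length(p)) < p)
    jitter <- runif(length(hit), 0, dt * 0.999)
  })
  spike_train(tms[hit] + jitter)
}

#' Spike-train container
#'
#' @param spike_time Non-negative, strictly increasing spike times (s).
#' @param unit_id Unit label.
#' @return Tibble of class `spike_train` with columns `spike_time`, `unit_id`.
#' @export
spike_train <- function(spike_time, unit_id = "u1") {
  spike_time <- as.numeric(spike_time)
  if (any(!is.finite(spike_time)) || any(spike_time < 0))
    abort("spike times must be finite and non-negative", class = "phasestim_data_error")
  if (is.unsorted(spike_time, strictly = TRUE))
    abort("spike times must be strictly increasing", class = "phasestim_data_error")
  out <- tibble(spike_time = spike_time,
                unit_id = rep_len(as.character(unit_id), length(spike_time)))
  class(out) <- c("spike_train", class(out))
  out
}

#' Insert stimulation-evoked spikes into a spike train
#'
#' For each stimulation event, with probability `spec$evoked_probability`
#' one extra spike is inserted `spec$evoked_latency_ms` after the delivery
#' time. The result is re-sorted and de-duplicated.
#'
#' @param spikes A [spike_train()] (or numeric spike times).
#' @param events A tibble of stimulation events with a `delivery_time`
#'   column (see [run_closed_loop()]).
#' @param spec A [spike_spec()].
#' @param seed Integer seed.
#' @return A [spike_train()].
#' @export
apply_evoked_spikes <- function(spikes, events, spec, seed = 1L) {
  stopifnot(inherits(spec, "spike_spec"))
  if (is.numeric(spikes)) spikes <- spike_train(spikes)
  if (!"delivery_time" %in% names(events))
    abort("`events` needs a `delivery_time` column", class = "phasestim_data_error")
  withr::with_seed(as.integer(seed), {
    hit <- runif(nrow(events)) < spec$evoked_probability
  })
  extra <- events$delivery_time[hit] + spec$evoked_latency_ms / 1000
  all_t <- sort(unique(c(spikes$spike_time, extra)))
  spike_train(all_t, unit_id = if (nrow(spikes)) spikes$unit_id[1] else "u1")
}

#' Generate a smooth 3-D head trajectory over condition epochs
#'
#' Velocity follows an Ornstein--Uhlenbeck process per axis (correlation
#' time `spec$smoothness`); within each epoch its stationary scale is set
#' so the expected speed equals `baseline_speed` times the epoch
#' condition's multiplier. Gaps between epochs use multiplier 1.
#'
#' @param epochs An [epoch_set()].
#' @param spec A [motion_spec()]; conditions missing from
#'   `condition_speed_multipliers` default to 1.
#' @param seed Integer seed.
#' @return A tibble of class `head_trajectory` with columns `time`, `x`,
#'   `y`, `z` (mm), sampled at `spec$frame_rate` from 0 to the last epoch
#'   end; the frame rate is stored in attribute `frame_rate`.
#' @export
generate_head_trajectory <- function(epochs, spec, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(spec, "motion_spec"))
  dt <- 1 / spec$frame_rate
  t_end <- max(epochs$end)
  tms <- seq(0, t_end, by = dt)
  n <- length(tms)
  mult <- rep(1, n)
  for (i in seq_len(nrow(epochs))) {
    m <- spec$condition_speed_multipliers[[epochs$condition[i]]]
    if (is.null(m)) m <- 1
    mult[tms >= epochs$start[i] & tms < epochs$end[i]] <- m
  }
  # E|v| for 3-D isotropic Gaussian velocity with per-axis SD s is
  # s * 2*sqrt(2/pi); invert to hit the target mean speed
  target <- spec$baseline_speed * mult
  s_axis <- target / (2 * sqrt(2 / pi))
  alpha <- exp(-dt / spec$smoothness)
  innov_sd <- sqrt(1 - alpha^2)
  withr::with_seed(as.integer(seed), {
    v <- matrix(0, n, 3)
    for (ax in 1:3) {
      u <- stats::filter(rnorm(n, 0, innov_sd), alpha, method = "recursive")
      v[, ax] <- as.numeric(u) * s_axis   # unit OU scaled per-frame to target
    }
  })
  pos <- apply(v * dt, 2, cumsum)
  out <- tibble(time = tms, x = pos[, 1], y = pos[, 2], z = pos[, 3])
  attr(out, "frame_rate") <- spec$frame_rate
  class(out) <- c("head_trajectory", class(out))
  out
}
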