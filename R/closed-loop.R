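# Simulated closed loop: buffered streaming, latency accounting,
# phase-targeted trigger decisions, and offline accuracy scoring.

#' Total latency of the closed-loop chain
#'
#' Sum of the five delay components in milliseconds. With the default
#' component medians (0, 10.00, 2.05, 0.21, 0.74) this is exactly 13.00 ms
#' -- under the 50 ms period of a 20 Hz rhythm, so the loop can target beta
#' phase.
#'
#' @param latency A [latency_model()].
#' @return Total latency in ms.
#' @export
total_latency <- function(latency) {
  stopifnot(inherits(latency, "latency_model"))
  latency$acquisition_ms + latency$buffer_ms + latency$compute_ms +
    latency$transport_ms + latency$actuator_rise_ms
}

#' Period of an oscillation frequency
#'
#' @param frequency Frequency in Hz (> 0).
#' @return Period in milliseconds (e.g. 50 ms at 20 Hz).
#' @export
period_ms <- function(frequency) {
  if (any(frequency <= 0)) abort("`frequency` must be > 0", class = "phasestim_config_error")
  1000 / frequency
}

#' Run the simulated closed loop over a signal
#'
#' Replays the real-time pipeline offline. Data arrive in hops of
#' `latency$buffer_ms`; at each hop the controller forms the causal wavelet
#' estimate at the newest coverable center (window end minus the kernel
#' half-length), predicts the phase at the moment a pulse commanded now
#' would be delivered (`hop time + compute + transport + actuator rise`),
#' and fires when the prediction is close enough to the target, the
#' amplitude gate passes, and the refractory interval has elapsed.
#'
#' The firing window is `min(phase_tolerance, pi * f * hop)`: capping the
#' tolerance at half the per-hop phase advance centers deliveries on the
#' target instead of biasing them toward the early edge of the window.
#' The prediction horizon spans from the kernel-center time to the
#' delivery time, so the wavelet group lag and the hardware latency are
#' compensated together; on a noiseless constant-frequency signal the
#' achieved phase is therefore independent of the latency budget.
#'
#' With `target_phase = "random"` the phase test is replaced by a
#' Bernoulli draw with per-hop probability `f0 * hop` (matching the
#' one-pulse-per-cycle expected rate), giving the phase-random control.
#'
#' @param signal A [continuous_signal()] longer than the kernel plus one
#'   buffer.
#' @param policy A [stim_policy()].
#' @param latency A [latency_model()].
#' @param seed Integer seed (used only by the random-phase policy).
#' @param hop_ms Decision interval in ms; defaults to `latency$buffer_ms`
#'   (non-overlapping hops).
#' @return A tibble of class `stim_events`, one row per pulse:
#'   `command_time`, `delivery_time` (s), `pulse_width_ms`, `target_phase`
#'   (NA under the random policy), `predicted_phase`, `true_phase` (NA
#'   until filled by [evaluate_phase_accuracy()]).
#' @export
run_closed_loop <- function(signal, policy, latency, seed = 1L, hop_ms = NULL) {
  stopifnot(inherits(signal, "continuous_signal"),
            inherits(policy, "stim_policy"),
            inherits(latency, "latency_model"))
  band <- policy$band
  f0 <- band$center_frequency
  if (total_latency(latency) > period_ms(f0) + policy$phase_tolerance / (2 * pi * f0) * 1000)
    warn(sprintf(paste0("total latency %.2f ms exceeds one %g Hz period; ",
                        "prediction wraps across cycles"),
                 total_latency(latency), f0))
  if (is.null(hop_ms)) hop_ms <- latency$buffer_ms
  hop_s <- hop_ms / 1000
  fs <- signal$sampling_rate
  n <- length(signal$samples)
  ws <- wavelet_transform(signal, band)
  nh <- ws$kernel$n_half
  if (n < 2 * nh + 1 + round(hop_s * fs))
    abort("signal shorter than kernel plus one buffer", class = "phasestim_data_error")

  t_end <- signal$start_time + (n - 1) / fs
  acq_s <- latency$acquisition_ms / 1000
  cmd_delay_s <- (latency$compute_ms + latency$transport_ms +
                    latency$actuator_rise_ms) / 1000
  span <- max(1L, round(0.025 * fs))
  hops <- seq(signal$start_time + hop_s, t_end, by = hop_s)
  newest <- floor((hops - acq_s - signal$start_time) * fs) + 1
  centers <- newest - nh
  ok <- centers - span >= ws$valid[1] & newest <= n
  hops <- hops[ok]; centers <- centers[ok]
  if (!length(hops)) abort("signal too short for any decision hop",
                           class = "phasestim_data_error")

  co <- ws$coef[centers]
  amp <- Mod(co) / ws$kernel$amp_scale
  phase <- Arg(co)
  freq <- .wavelet_frequency(ws, centers)
  center_time <- signal$start_time + (centers - 1) / fs
  delivery <- hops + cmd_delay_s
  horizon <- delivery - center_time
  pred <- wrap_phase(phase + 2 * pi * freq * horizon)

  eligible <- amp >= policy$amplitude_gate & amp >= 1e-12
  if (policy$random) {
    withr::with_seed(as.integer(seed), {
      fire_p <- min(1, f0 * hop_s)
      eligible <- eligible & runif(length(hops)) < fire_p
    })
  } else {
    win <- pmin(policy$phase_tolerance, pi * freq * hop_s)
    eligible <- eligible & abs(circ_diff(pred, policy$target_phase)) <= win
  }
  eligible <- eligible & delivery <= t_end

  cand <- which(eligible)
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {            # refractory scan over candidates only
    if (delivery[i] - last >= policy$refractory_s - 1e-12) {
      keep <- c(keep, i)
      last <- delivery[i]
    }
  }
  out <- tibble(
    command_time = hops[keep],
    delivery_time = delivery[keep],
    pulse_width_ms = policy$pulse_width_ms,
    target_phase = if (policy$random) NA_real_ else policy$target_phase,
    predicted_phase = pred[keep],
    true_phase = NA_real_
  )
  class(out) <- c("stim_events", class(out))
  attr(out, "band") <- band
  out
}

#' Score achieved stimulation phase against offline ground truth
#'
#' Fills each event's `true_phase` from the acausal oracle
#' ([acausal_phase()] over the band's passband) at the delivery time, and
#' summarizes the wrapped differences `true - target` with circular
#' statistics: the circular average (argument of the mean resultant
#' vector) and a quartile dispersion interval around it. Events without a
#' target (random-phase policy) are referenced to 0 rad, i.e. their raw
#' achieved phase enters the summary.
#'
#' @param events A [run_closed_loop()] result (>= 1 row) within the
#'   signal's support.
#' @param signal The [continuous_signal()] the loop ran on.
#' @param band A [band_spec()]; its `passband` defines the oracle filter.
#' @return A list of class `phase_accuracy`: `events` (tibble with
#'   `true_phase` and `phase_diff` filled), `circular_average`,
#'   `dispersion_interval` (`q1`, `q3`), `resultant_length`, `n_events`.
#' @export
evaluate_phase_accuracy <- function(events, signal, band) {
  stopifnot(inherits(signal, "continuous_signal"), inherits(band, "band_spec"))
  if (!is.data.frame(events) || nrow(events) == 0)
    abort("`events` must contain at least one event", class = "phasestim_data_error")
  tms <- signal_times(signal)
  if (any(events$delivery_time < tms[1] - 1e-9) ||
      any(events$delivery_time > tms[length(tms)] + 1e-9))
    abort("events fall outside the signal support", class = "phasestim_data_error")
  oracle <- acausal_phase(signal, band$passband)
  idx <- .signal_index(signal, events$delivery_time)
  truth <- oracle$phase[idx]
  ref <- ifelse(is.na(events$target_phase), 0, events$target_phase)
  diffs <- circ_diff(truth, ref)
  ev <- events
  ev$true_phase <- truth
  ev$phase_diff <- diffs
  structure(list(events = ev,
                 circular_average = circ_mean(diffs),
                 dispersion_interval = circ_quartiles(diffs),
                 resultant_length = circ_r(diffs),
                 n_events = nrow(ev),
                 band = band),
            class = "phase_accuracy")
}

#' @export
print.phase_accuracy <- function(x, ...) {
  q <- x$dispersion_interval
  cat(sprintf(paste0("<phase_accuracy> %d events @ %g Hz: circular average ",
                     "%.3f rad (quartiles %.2f to %.2f)\n"),
              x$n_events, x$band$center_frequency,
              x$circular_average, q[["q1"]], q[["q3"]]))
  invisible(x)
}
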