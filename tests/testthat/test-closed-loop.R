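test_that("total_latency sums the five components", {
  expect_equal(total_latency(latency_model(0, 10, 2.05, 0.21, 0.74)), 13.00)
  expect_equal(total_latency(latency_model(0.1, 10, 2, 0.2, 0.7)), 13.0)
  expect_equal(total_latency(latency_model(0, 1e-9, 0, 0, 0)), 1e-9)
  expect_error(latency_model(compute_ms = -1), class = "phasestim_config_error")
})

test_that("period_ms returns 50 ms at 20 Hz and rejects non-positive input", {
  expect_identical(period_ms(20), 50)
  expect_equal(period_ms(4), 250)
  expect_error(period_ms(0), class = "phasestim_config_error")
})

test_that("ideal loop: noiseless 4 Hz, zero extra latency, target peak", {
  sig <- generate_lfp(oscillator_spec(4), noise_spec(1, 0), 30, 1000, seed = 1)
  pol <- stim_policy(band_spec(4), target_phase = 0, phase_tolerance = 0.2)
  ev <- run_closed_loop(sig, pol, latency_model(0, 10, 0, 0, 0))
  expect_gt(nrow(ev), 50)
  expect_lte(nrow(ev) / 30, 4)          # at most one pulse per cycle
  truth <- sig$truth$phase_1[round(ev$delivery_time * 1000) + 1]
  expect_true(all(abs(circ_diff(truth, 0)) <= 0.2))
})

test_that("20 Hz trough targeting under the 13 ms budget hits pi on average", {
  sig <- generate_lfp(oscillator_spec(20, frequency_jitter_sd = 0.3),
                      noise_spec(1, 0), 120, 1000, seed = 2)
  b <- band_spec(20)
  ev <- run_closed_loop(sig, stim_policy(b, target_phase = pi), latency_model())
  expect_gt(nrow(ev), 100)
  acc <- evaluate_phase_accuracy(ev, sig, b)
  # achieved phases (oracle) sit at the trough: mean difference ~ 0
  expect_lt(abs(acc$circular_average), 0.1)
  truth_mean <- circ_mean(acc$events$true_phase)
  expect_lt(abs(circ_diff(truth_mean, pi)), 0.1)
})

test_that("amplitude gate above the signal amplitude silences the loop", {
  sig <- generate_lfp(oscillator_spec(4), noise_spec(1, 0), 10, 1000, seed = 3)
  pol <- stim_policy(band_spec(4), target_phase = 0, amplitude_gate = 10)
  ev <- run_closed_loop(sig, pol, latency_model())
  expect_equal(nrow(ev), 0)
})

test_that("refractory interval is never violated across policies and seeds", {
  sig4 <- snr2_lfp(4, 60, seed = 4)
  for (target in list(0, pi, "random")) {
    for (s in 1:3) {
      pol <- stim_policy(band_spec(4), target_phase = target)
      ev <- run_closed_loop(sig4, pol, latency_model(), seed = s)
      if (nrow(ev) > 1)
        expect_gte(min(diff(ev$delivery_time)), pol$refractory_s - 1e-9)
      expect_true(all(diff(ev$command_time) > 0))
      expect_true(all(ev$delivery_time >= ev$command_time))
    }
  }
})

test_that("achieved phase is independent of total latency on noiseless signals", {
  sig <- generate_lfp(oscillator_spec(4), noise_spec(1, 0), 60, 1000, seed = 5)
  b <- band_spec(4)
  lats <- list(latency_model(0, 10, 0, 0, 0),
               latency_model(0, 10, 2.05, 0.21, 0.74),
               latency_model(0, 10, 25, 10, 5))
  avgs <- sapply(lats, function(l) {
    ev <- run_closed_loop(sig, stim_policy(b, 0), l)
    evaluate_phase_accuracy(ev, sig, b)$circular_average
  })
  expect_lt(max(abs(circ_diff(avgs, avgs[1]))), 0.1)
})

test_that("achieved-phase dispersion does not decrease with noise", {
  disp <- sapply(c(0.2, 0.5, 1.0), function(ns) {
    median(sapply(1:5, function(s) {
      sig <- generate_lfp(oscillator_spec(4, frequency_jitter_sd = 0.5),
                          noise_spec(1, ns), 60, 1000, seed = s)
      b <- band_spec(4)
      ev <- run_closed_loop(sig, stim_policy(b, 0), latency_model())
      1 - evaluate_phase_accuracy(ev, sig, b)$resultant_length
    }))
  })
  expect_true(all(diff(disp) >= 0))
})

test_that("random-phase policy yields circularly uniform achieved phases", {
  sig <- generate_lfp(oscillator_spec(4), noise_spec(1, 0), 120, 1000, seed = 6)
  b <- band_spec(4)
  ev <- run_closed_loop(sig, stim_policy(b, "random"), latency_model(), seed = 7)
  expect_gt(nrow(ev), 100)
  expect_true(all(is.na(ev$target_phase)))
  acc <- evaluate_phase_accuracy(ev, sig, b)
  # Rayleigh fails to reject uniformity at alpha = 0.01
  expect_gt(rayleigh_test(acc$events$true_phase)$p.value, 0.01)
})

test_that("evaluate_phase_accuracy scores hand-placed events exactly", {
  sig <- generate_lfp(oscillator_spec(4), noise_spec(1, 0), 30, 1000, seed = 8)
  b <- band_spec(4)
  peaks <- seq(2, 28, by = 0.25)     # t with 4t integer: true peaks
  mk <- function(times, target) tibble::tibble(
    command_time = times - 0.003, delivery_time = times, pulse_width_ms = 5,
    target_phase = target, predicted_phase = target, true_phase = NA_real_)
  acc_peak <- evaluate_phase_accuracy(mk(peaks, 0), sig, b)
  expect_lt(abs(acc_peak$circular_average), 0.05)
  expect_lt(max(abs(acc_peak$events$phase_diff)), 0.1)
  # events at troughs scored against a peak target sit at pi
  troughs <- peaks + 0.125
  acc_anti <- evaluate_phase_accuracy(mk(troughs, 0), sig, b)
  expect_lt(abs(circ_diff(acc_anti$circular_average, pi)), 0.05)
  expect_error(evaluate_phase_accuracy(mk(numeric(0), 0), sig, b),
               class = "phasestim_data_error")
})

test_that("tidiers expose per-event rows and a one-row circular summary", {
  sig <- snr2_lfp(4, 30, seed = 9)
  b <- band_spec(4)
  ev <- run_closed_loop(sig, stim_policy(b, 0), latency_model())
  acc <- evaluate_phase_accuracy(ev, sig, b)
  td <- tidy(acc)
  expect_equal(nrow(td), acc$n_events)
  expect_true(all(c("delivery_time", "true_phase", "phase_diff") %in% names(td)))
  gl <- glance(acc)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$circular_average, acc$circular_average)
})
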