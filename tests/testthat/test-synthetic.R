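test_that("noiseless single oscillator is an exact cosine with exact truth", {
  sig <- generate_lfp(oscillator_spec(4, amplitude = 1), noise_spec(1, 0),
                      duration = 1, sampling_rate = 1000, seed = 1)
  t <- signal_times(sig)
  expect_equal(length(sig$samples), 1000)
  expect_equal(sig$samples, cos(2 * pi * 4 * t), tolerance = 1e-12)
  expect_identical(sig$truth$phase_1[1], 0)
  expect_equal(sig$truth$phase_1, wrap_phase(2 * pi * 4 * t), tolerance = 1e-9)
})

test_that("pure 1/f noise has log-log PSD slope near -1 over 1-100 Hz", {
  sig <- generate_lfp(list(), noise_spec(exponent = 1, scale = 1),
                      duration = 10, sampling_rate = 1000, seed = 2)
  slope <- loglog_psd_slope(sig$samples, 1000, 1, 100)
  expect_gt(slope, -1.3)
  expect_lt(slope, -0.7)
  expect_equal(sd(sig$samples), 1, tolerance = 1e-9)  # scale = broadband SD
})

test_that("all four generators are bit-identical under equal seeds", {
  osc <- oscillator_spec(4, frequency_jitter_sd = 0.5, amplitude_jitter_sd = 0.1)
  a <- generate_lfp(osc, noise_spec(1, 0.5), 5, 1000, seed = 42)
  b <- generate_lfp(osc, noise_spec(1, 0.5), 5, 1000, seed = 42)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)

  ph <- data.frame(time = a$truth$time, phase = a$truth$phase_1)
  s1 <- generate_phase_locked_spikes(ph, spike_spec(10, 2), seed = 7)
  s2 <- generate_phase_locked_spikes(ph, spike_spec(10, 2), seed = 7)
  expect_identical(s1, s2)

  ev <- tibble::tibble(delivery_time = seq(0.5, 4.5, by = 0.5))
  e1 <- apply_evoked_spikes(s1, ev, spike_spec(10, evoked_probability = 0.5), seed = 8)
  e2 <- apply_evoked_spikes(s1, ev, spike_spec(10, evoked_probability = 0.5), seed = 8)
  expect_identical(e1, e2)

  ep <- epoch_set(0, 30, "no_stim")
  t1 <- generate_head_trajectory(ep, motion_spec(), seed = 9)
  t2 <- generate_head_trajectory(ep, motion_spec(), seed = 9)
  expect_identical(t1, t2)
})

test_that("single-oscillator LFP shows a PSD peak at the center frequency", {
  sig <- generate_lfp(oscillator_spec(7), noise_spec(1, 0.2), 30, 1000, seed = 3)
  psd <- compute_psd(sig, segment_s = 4)
  pk <- psd$frequency[which.max(psd$power)]
  expect_lte(abs(pk - 7), 0.25)    # within one frequency bin
  # a wandering oscillator still peaks inside its reflection band
  sigj <- generate_lfp(oscillator_spec(7, frequency_jitter_sd = 0.2,
                                       reflect_halfwidth = 1),
                       noise_spec(1, 0.2), 30, 1000, seed = 3)
  psdj <- compute_psd(sigj, segment_s = 4)
  pkj <- psdj$frequency[which.max(psdj$power)]
  expect_true(pkj >= 6 && pkj <= 8)
})

test_that("ground-truth phase matches the acausal Hilbert oracle on noiseless signals", {
  sig <- generate_lfp(oscillator_spec(4, frequency_jitter_sd = 0.5),
                      noise_spec(1, 0), 60, 1000, seed = 4)
  oracle <- acausal_phase(sig, c(2, 8))
  core <- 2000:58000   # exclude filter edges
  expect_lt(circ_rmse(sig$truth$phase_1[core], oracle$phase[core]), 0.05)
})

test_that("spike generator: kappa = 0 limit is homogeneous Poisson at base_rate", {
  sig <- generate_lfp(oscillator_spec(4), noise_spec(1, 0), 100, 1000, seed = 5)
  ph <- data.frame(time = sig$truth$time, phase = sig$truth$phase_1)
  sp <- generate_phase_locked_spikes(ph, spike_spec(base_rate = 10, 0), seed = 6)
  rate <- nrow(sp) / 100
  se <- sqrt(10 / 100)   # Poisson SE of the rate estimate
  expect_lt(abs(rate - 10), 3 * se)
  expect_false(is.unsorted(sp$spike_time, strictly = TRUE))
})

test_that("spike phases concentrate at the preferred phase, matching a von Mises oracle", {
  sig <- generate_lfp(oscillator_spec(4), noise_spec(1, 0), 100, 1000, seed = 7)
  ph <- data.frame(time = sig$truth$time, phase = sig$truth$phase_1)
  sp <- generate_phase_locked_spikes(ph, spike_spec(10, locking_concentration = 5),
                                     seed = 8)
  expect_gt(nrow(sp), 500)
  idx <- round(sp$spike_time * 1000) + 1
  sp_phase <- sig$truth$phase_1[pmin(idx, nrow(sig$truth))]
  expect_lt(abs(circ_diff(circ_mean(sp_phase), 0)), 0.1)
  # oracle: direct von Mises sample via rejection, same concentration
  withr::with_seed(9, {
    cand <- runif(40000, -pi, pi)
    vm <- cand[runif(40000) < exp(5 * (cos(cand) - 1))][1:1000]
  })
  expect_lt(abs(circ_diff(circ_mean(vm), circ_mean(sp_phase))), 0.1)
  # concentration of the generated spikes is comparable to the oracle's
  expect_lt(abs(circ_r(sp_phase) - circ_r(vm)), 0.1)
})

test_that("zero base rate gives an empty spike train", {
  sig <- generate_lfp(oscillator_spec(4), noise_spec(1, 0), 1, 1000, seed = 1)
  ph <- data.frame(time = sig$truth$time, phase = sig$truth$phase_1)
  sp <- generate_phase_locked_spikes(ph, spike_spec(base_rate = 0), seed = 1)
  expect_equal(nrow(sp), 0)
})

test_that("spike-phase concentration increases monotonically in kappa", {
  kappas <- c(0, 1, 2, 5)
  med_r <- sapply(kappas, function(k) {
    rs <- sapply(1:10, function(s) {
      sig <- generate_lfp(oscillator_spec(4), noise_spec(1, 0), 100, 250, seed = s)
      ph <- data.frame(time = sig$truth$time, phase = sig$truth$phase_1)
      sp <- generate_phase_locked_spikes(ph, spike_spec(8, k), seed = s + 100)
      idx <- pmin(round(sp$spike_time * 250) + 1, nrow(sig$truth))
      circ_r(sig$truth$phase_1[idx])
    })
    median(rs)
  })
  expect_true(all(diff(med_r) > 0))
})

test_that("evoked spikes: counts and latencies follow the binomial model", {
  base <- spike_train(seq(0.1, 99.9, by = 0.1))
  ev10 <- tibble::tibble(delivery_time = seq(1, 10, by = 1) + 0.05)
  sp <- spike_spec(base_rate = 10, evoked_probability = 1, evoked_latency_ms = 3)
  out <- apply_evoked_spikes(base, ev10, sp, seed = 1)
  expect_equal(nrow(out) - nrow(base), 10)
  added <- setdiff(out$spike_time, base$spike_time)
  expect_true(all(sapply(added, function(a)
    min(abs(a - ev10$delivery_time)) < 0.005)))

  sp0 <- spike_spec(base_rate = 10, evoked_probability = 0)
  expect_identical(apply_evoked_spikes(base, ev10, sp0, seed = 1)$spike_time,
                   base$spike_time)

  ev1000 <- tibble::tibble(delivery_time = seq(0.05, 99.95, length.out = 1000))
  sp5 <- spike_spec(base_rate = 10, evoked_probability = 0.5)
  out5 <- apply_evoked_spikes(base, ev1000, sp5, seed = 2)
  n_add <- nrow(out5) - nrow(base)
  se <- sqrt(1000 * 0.5 * 0.5)
  expect_lt(abs(n_add - 500), 3 * se)
  expect_false(is.unsorted(out5$spike_time, strictly = TRUE))
})

test_that("head trajectory hits per-condition target speeds", {
  # eight 30-s epochs per condition to average out OU sampling noise
  conds <- rep(c("no_stim", "peak", "trough"), times = 8)
  n <- length(conds)
  ep <- epoch_set((seq_len(n) - 1) * 30, seq_len(n) * 30, conds)
  ms <- motion_spec(frame_rate = 120, baseline_speed = 20,
                    condition_speed_multipliers = list(no_stim = 1, peak = 0.93,
                                                       trough = 1.4))
  tr <- generate_head_trajectory(ep, ms, seed = 21)
  es <- epoch_speeds(tr, ep, smoothing_window_frames = 1)
  m <- tapply(es$mean_speed, es$condition, mean)
  ratio <- m[["trough"]] / m[["peak"]]
  expect_lt(abs(ratio - 1.4 / 0.93) / (1.4 / 0.93), 0.1)
  # all-equal multipliers: condition means agree within 10%
  ms1 <- motion_spec(120, 20, list(no_stim = 1, peak = 1, trough = 1))
  es1 <- epoch_speeds(generate_head_trajectory(ep, ms1, seed = 22), ep,
                      smoothing_window_frames = 1)
  m1 <- tapply(es1$mean_speed, es1$condition, mean)
  expect_lt((max(m1) - min(m1)) / min(m1), 0.1)
})

test_that("zero baseline speed gives a stationary trajectory", {
  ep <- epoch_set(0, 10, "no_stim")
  tr <- generate_head_trajectory(ep, motion_spec(baseline_speed = 0), seed = 1)
  sp <- head_speed(tr)
  expect_true(all(sp$speed == 0))
})

test_that("generator input validation rejects bad specs and rates", {
  expect_error(oscillator_spec(-4), class = "phasestim_config_error")
  expect_error(noise_spec(exponent = 5), class = "phasestim_config_error")
  expect_error(spike_spec(evoked_probability = 2), class = "phasestim_config_error")
  expect_error(generate_lfp(oscillator_spec(20), noise_spec(), 1,
                            sampling_rate = 50), # below 4x Nyquist margin
               class = "phasestim_config_error")
  expect_error(generate_lfp(oscillator_spec(4), noise_spec(), duration = -1,
                            sampling_rate = 1000),
               class = "phasestim_config_error")
  expect_error(epoch_set(c(0, 5), c(10, 15), c("no_stim", "peak")),
               class = "phasestim_data_error")
})
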