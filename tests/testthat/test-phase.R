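test_that("Morlet kernel is unit-norm, zero-mean, centered, and scales with frequency", {
  k4 <- morlet_kernel(band_spec(4, n_cycles = 7, passband = c(2, 8)), 1000)
  expect_equal(sum(Mod(k4$values)^2), 1, tolerance = 1e-9)
  expect_lt(Mod(mean(k4$values)), 1e-12)
  expect_equal(which.max(Mod(k4$values)), k4$n_half + 1)
  # inner product with a peak-aligned cosine has argument ~0
  t <- (-k4$n_half:k4$n_half) / 1000
  coef <- sum(cos(2 * pi * 4 * t) * Conj(k4$values))
  expect_lt(abs(Arg(coef)), 0.02)
  # duration inversely proportional to frequency at equal n_cycles
  k20 <- morlet_kernel(band_spec(20, n_cycles = 7), 1000)
  expect_lt(k20$duration_s, k4$duration_s)
  expect_equal(k20$duration_s / k4$duration_s, 4 / 20, tolerance = 0.01)
  expect_error(morlet_kernel(band_spec(20), 50), class = "phasestim_config_error")
})

test_that("estimate_phase recovers phase, frequency, and quadrature of pure tones", {
  b <- band_spec(4)
  # the estimate refers to the newest kernel-coverable center: half a
  # kernel (0.5 s at 4 Hz) before the window end
  est <- estimate_phase(pure_tone(4, 1.5), b)
  expect_equal(est$time, 1.5 - 1 / 1000 - 0.5)
  expect_lt(abs(circ_diff(est$phase, wrap_phase(2 * pi * 4 * est$time))), 0.05)
  expect_lt(abs(est$frequency - 4), 0.1)
  expect_equal(est$amplitude, 1, tolerance = 0.02)
  expect_false(est$undefined)
  # sine = cosine delayed by pi/2
  est_sin <- estimate_phase(pure_tone(4, 1.5, phase0 = -pi / 2), b)
  expect_lt(abs(circ_diff(est_sin$phase,
                          wrap_phase(2 * pi * 4 * est_sin$time - pi / 2))), 0.05)
  # off-center tone: frequency tracks the tone, not the kernel center
  est5 <- estimate_phase(pure_tone(5, 1.5), b)
  expect_lt(abs(est5$frequency - 5), 0.15)
})

test_that("all-zero window yields amplitude 0 with an undefined-phase flag", {
  z <- continuous_signal(rep(0, 2000), 1000)
  est <- estimate_phase(z, band_spec(4))
  expect_true(est$undefined)
  expect_equal(est$amplitude, 0)
  expect_true(is.na(est$phase))
})

test_that("windows shorter than the kernel are rejected", {
  expect_error(estimate_phase(pure_tone(4, 0.5), band_spec(4)),
               class = "phasestim_data_error")
})

test_that("wavelet phase tracks the Hilbert oracle on stationary band-limited signals", {
  # stationary: constant frequency and amplitude, 1/f noise at SNR 2
  sig <- generate_lfp(oscillator_spec(4), noise_spec(1, 0.5), 60, 1000, seed = 31)
  noiseless <- generate_lfp(oscillator_spec(4, frequency_jitter_sd = 0.5),
                            noise_spec(1, 0), 60, 1000, seed = 31)
  b <- band_spec(4)
  core <- 3000:57000
  # noiseless: < 0.1 rad circular RMSE against the acausal oracle
  wv0 <- as_tibble(wavelet_transform(noiseless, b))
  or0 <- acausal_phase(noiseless, b$passband)
  expect_lt(circ_rmse(wv0$phase[core], or0$phase[core]), 0.1)
  # amplitude SNR 2: < 0.3 rad
  wv <- as_tibble(wavelet_transform(sig, b))
  or <- acausal_phase(sig, b$passband)
  expect_lt(circ_rmse(wv$phase[core], or$phase[core]), 0.3)
})

test_that("phase prediction is consistent with later estimation on constant-frequency signals", {
  b <- band_spec(4)
  sig <- pure_tone(4, 3)
  for (delta in c(0.005, 0.013, 0.050)) {
    est_now <- estimate_phase(signal_window(sig, 0, 2), b)
    est_later <- estimate_phase(signal_window(sig, 0, 2 + delta), b)
    pred <- predict_phase(est_now, delta)
    expect_lt(abs(circ_diff(pred, est_later$phase)), 0.05)
  }
})

test_that("predict_phase closed forms and argument checks", {
  expect_equal(predict_phase(list(phase = 0, frequency = 4), 0.05),
               wrap_phase(0.4 * pi), tolerance = 1e-12)
  expect_equal(predict_phase(list(phase = 0, frequency = 20), 0.05), 0,
               tolerance = 1e-12)
  withr::with_seed(32, ph <- runif(20, -pi, pi))
  expect_equal(predict_phase(list(phase = ph, frequency = 4), 0), ph)
  expect_error(predict_phase(list(phase = 0, frequency = 4), -0.01),
               class = "phasestim_config_error")
})

test_that("estimated amplitude increases monotonically with true amplitude", {
  amps <- c(0.25, 0.5, 1, 2, 4)
  med_est <- sapply(amps, function(a) {
    median(sapply(1:10, function(s) {
      sig <- generate_lfp(oscillator_spec(4, amplitude = a), noise_spec(1, 0.5),
                          duration = 5, sampling_rate = 1000, seed = s)
      estimate_phase(sig, band_spec(4))$amplitude
    }))
  })
  expect_true(all(diff(med_est) > 0))
})
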