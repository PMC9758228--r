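# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except in the I/O round-trip tests, which write to
# tempfiles.

# pure tone as a continuous_signal
pure_tone <- function(f, duration = 3, fs = 1000, phase0 = 0, amplitude = 1) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  continuous_signal(amplitude * cos(2 * pi * f * t + phase0), fs)
}

# the study-condition synthetic LFP: target oscillator at amplitude SNR 2
# over 1/f noise (amplitude 1, noise SD 0.5)
snr2_lfp <- function(f0, duration, seed, fs = 1000) {
  generate_lfp(
    oscillator_spec(f0, amplitude = 1,
                    frequency_jitter_sd = if (f0 < 10) 0.5 else 1,
                    amplitude_jitter_sd = 0.1),
    noise_spec(exponent = 1, scale = 0.5),
    duration = duration, sampling_rate = fs, seed = seed
  )
}

# least-squares log-log PSD slope over a frequency range (independent of
# compute_psd): raw periodogram on the full signal
loglog_psd_slope <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  P <- Mod(stats::fft(x - mean(x)))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= f_lo & f <= f_hi
  stats::coef(stats::lm(log10(P[keep]) ~ log10(f[keep])))[[2]]
}
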