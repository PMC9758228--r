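---
title: "Phase-adaptive closed-loop stimulation: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-adaptive closed-loop stimulation: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasestim)
```

## The problem

A closed-loop stimulator that targets the phase of an ongoing brain
rhythm must solve three coupled problems: estimate the instantaneous
phase of a narrow band *causally* (using only past samples), predict the
phase forward across the system's latency budget, and decide when to
fire. `phasestim` implements this loop for low-frequency (~4 Hz) and
beta (~20 Hz) rhythms of the kind recorded in the dorsal striatum of
dopamine-depleted mice, together with the offline analytics used to
judge such a system, and a synthetic-data module that makes all of it
testable at the desk.

Phases follow the cosine convention throughout: 0 rad is an oscillation
peak, π rad a trough, and all angles live in (−π, π].

## Causal phase estimation

The estimator is a complex Morlet wavelet: a Gaussian-windowed complex
exponential with temporal SD `n_cycles / (2π f0)`, truncated at
`n_cycles / f0` seconds (≈ ±3 SD), mean-subtracted so it integrates to
zero, and L2-normalized. The inner product of the kernel with a signal
window gives the band coefficient; its argument is the phase and its
magnitude, divided by a stored calibration factor (the coefficient a
unit-amplitude tone at `f0` produces), the amplitude in signal units.

Two choices here are genuinely open and matter:

* **Kernel width.** Wider kernels select frequency better but look
  further into the past. Defaults are 4 cycles at 4 Hz and 7 cycles at
  20 Hz: a 4-cycle kernel at 4 Hz already spans 1 s, and since the
  centered kernel's newest usable estimate refers to half a kernel
  before the window end, its half-length (0.5 s at 4 Hz, 0.175 s at
  20 Hz) is a pure estimation lag. This lag is *not* hidden: the
  controller folds it into the prediction horizon, and it is the main
  reason prediction quality, not hardware latency, limits accuracy at
  4 Hz.
* **Instantaneous frequency.** "Linear estimation" of future phase needs
  a local frequency. We use the least-squares slope of the unwrapped
  wavelet phase over the trailing 25 ms of coefficients (6 points, 5 ms
  apart), clamped to the band's passband. A slope over many points is
  robust to single-coefficient noise; the passband clamp stops noise
  from extrapolating at impossible rates. The clamp bounds, default
  (2, 8) Hz and (16, 25) Hz, also define the offline oracle's filter.

Degenerate inputs are flagged, not fudged: a window with numerically
zero band amplitude returns `undefined = TRUE` and an `NA` phase, and
the controller treats flagged estimates as "do not fire".

## The closed loop

Samples arrive in buffer-sized hops (default 10 ms, the buffering delay
of the modeled acquisition chain). At each hop the controller:

1. forms the causal estimate at the newest coverable kernel center;
2. predicts the phase at delivery time
   `hop + compute + transport + actuator rise` via
   `wrap(φ + 2π f̂ Δ)`, where Δ runs from the *kernel center* to the
   delivery instant — this single bookkeeping step is what makes the
   achieved phase independent of the latency budget on stationary
   rhythms (a property the test suite checks at 0, 13, and 50 ms);
3. fires if the predicted delivery phase is within
   `min(phase_tolerance, π f̂ · hop)` of the target, the amplitude gate
   passes, and the refractory interval has elapsed.

The half-hop cap in step 3 deserves a note. A plain "fire when within
tolerance" rule triggers the first hop the prediction *enters* the
window, biasing deliveries early by roughly half the per-hop phase
advance (≈ 0.13 rad at 4 Hz with 10 ms hops). Capping the window at half
the per-hop advance makes "this hop is the closest approach to the
target" the actual criterion, centering the achieved-phase distribution
on the target. `phase_tolerance` (default 0.3 rad) remains the user's
outer bound; the refractory default of half a period bounds the pulse
rate at one per cycle.

The phase-random control replaces the phase test with a Bernoulli draw
at `f0 · hop` per hop, matching the expected one-per-cycle rate while
severing any phase dependence; the test suite verifies the achieved
phases pass a Rayleigh uniformity test.

Latency components default to the measured medians of a working system
of this architecture — acquisition ≈ 0 (< 0.1), buffer 10.00,
computation 2.05, transport 0.21, actuator rise 0.74 ms — whose exact
sum is 13.00 ms. (The corresponding published total, computed from
unrounded components, is 12.98 ms; `total_latency()` returns the exact
sum of its inputs and the 0.02 ms discrepancy is treated as rounding.)

## Offline scoring

Ground truth for "the phase a pulse actually hit" is the standard
acausal reference: a zero-phase band-pass over the band's passband
followed by the analytic signal (Hilbert) phase. The band-pass is a
frequency-domain brick wall with raised-cosine transitions (25% of each
edge frequency) rather than an IIR filter: it is exactly zero-phase, and
it is numerically robust at very low normalized frequencies (a 2–8 Hz
band at 1 kHz), where high-order recursive filters are fragile.
Accuracy summaries use the circular mean (argument of the mean resultant
vector) with a quartile interval obtained by rotating the sample onto
its mean; whether such figures should use a circular mean or median is
not settled usage, so the dispersion interval is always reported
alongside.

## Analytics

* **Spectra.** Welch averaged periodograms (Hann taper, demeaned
  segments, 50% overlap default), scaled so the integrated density
  matches the variance; band power is a trapezoidal integral.
* **Spike-field coherence.** Magnitude-squared coherence between the
  1-ms-binned, mean-subtracted spike train and the (bin-rate-resampled)
  LFP, accumulated Welch-style across windows. Windows with zero spikes
  carry no phase information and are excluded; if fewer than two
  windows survive, the value is *flagged undefined* — mirroring the
  indeterminate values time-resolved coherence produces on real data
  when a unit falls silent — never silently zero. The estimator is
  deliberately the plainest defensible one; because published absolute
  coherence values depend on estimator details (multitaper parameters,
  window lengths), only directions and contrasts should be compared
  across implementations.
* **Movement.** Speed is the Euclidean frame-to-frame displacement
  times the frame rate, smoothed with a 12-frame (100 ms at 120
  frames/s) moving average, matching the ~10 ms granularity of infrared
  tracking.
* **Contrasts.** Values are normalized per session to the
  no-stimulation condition, so conditions are unitless ratios around 1
  (this is how published peak/trough velocity ratios such as 0.93 and
  1.30 arise, and the normalization is explicit and optional). Medians
  and inter-quartile ranges are reported; the two-condition test is the
  two-sided Wilcoxon rank-sum, exact in the absence of ties (at n = 6
  per group, complete separation gives exactly 2/924 ≈ 0.002, the
  smallest two-sided p that design can produce), with midrank normal
  approximation under ties. Cohen's d uses the classic pooled-SD
  definition; the variant is stated because it is not standardized.

## What the generator emulates — and what it does not

The synthetic LFP is a sum of sinusoids whose instantaneous frequency
performs a reflected Gaussian random walk (diffusion `frequency_jitter_sd`
Hz per √s) around its center, bounded at ±min(center/2, 4) Hz so a 4 Hz
oscillator wanders within 2–6 Hz and a 20 Hz oscillator within 16–24 Hz
— inside their analysis passbands — plus Gaussian noise shaped to a
1/f^exponent spectrum with broadband SD `scale`. "Amplitude SNR 2" means
oscillator amplitude / noise SD = 2 (amplitude 1, scale 0.5). This
exposes exactly the nonstationarity a phase predictor must survive:
wandering frequency, waxing-waning amplitude, and broadband background.

Spiking is an inhomogeneous Poisson process with von Mises intensity
(`κ` the single locking knob; I0-normalized so the mean rate is
`base_rate` regardless of κ), thinned on the phase-trace grid;
stimulation adds one evoked spike per pulse with a configurable
probability at a 3 ms default latency, under the < 5 ms bound typical of
direct opsin activation. Head velocity is a 3-D Ornstein–Uhlenbeck
process whose stationary scale per epoch sets the expected speed to
`baseline_speed ×` the condition multiplier; the default multipliers
(peak 0.93, trough 1.30) emulate the velocity ratios this kind of
stimulation produces.

None of this is a biophysical striatal model. Passing tests show the
*machinery* is correct — estimation, prediction, triggering, scoring,
statistics — on signals with the right statistical structure; they do
not show that real striatal rhythms are sinusoids in 1/f noise, that
real D1-MSN locking is von Mises, or that biological effect sizes will
reproduce. Accordingly, published animal-level effect sizes are not
asserted anywhere; only directional and closed-form properties are.

## Numerical and scale choices

The generator's sampling default is 30 kHz, the native resolution of
the modeled acquisition hardware (24 kHz variants exist and are
accepted via configuration; neither is asserted as canonical). All
shipped analyses run at 1000 Hz — far above Nyquist for 4–25 Hz bands —
with 300 s sessions for phase-accuracy protocols, 60–120 s for
coherence and uniformity checks, and 30 s condition epochs in 2 blocks
for the default pipeline. These sizes put simulation error comfortably
below the assertion tolerances while keeping any single test in
seconds. Seeds are explicit everywhere; equal seeds give bit-identical
artifacts, and the pipeline manifest (config hash + seed + version)
makes every run reproducible.

Known limitations: single-channel estimation only (no multi-channel
fusion); hop-quantized firing (no sub-buffer scheduling), so achieved
phase carries a ±π f·hop quantization that the centered trigger makes
symmetric; phase-only linear prediction (the frequency estimate is held
constant over the horizon); and the modeled latency chain is a
deterministic budget, not a measured jitter distribution.
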