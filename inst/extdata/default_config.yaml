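# Default phasestim pipeline configuration (mirrors default_config()).
# A 4 Hz target rhythm (amplitude 1, slow frequency wander) in 1/f noise
# at amplitude SNR 2, sampled at 1000 Hz; measured-median latency budget
# (13.00 ms total); 30-s condition epochs in 2 blocks.
sampling_rate: 1000
band:
  center_frequency: 4
  n_cycles: 4
  passband: [2, 8]
oscillators:
  - center_frequency: 4
    amplitude: 1.0
    frequency_jitter_sd: 0.5
    amplitude_jitter_sd: 0.1
noise:
  exponent: 1
  scale: 0.5
latency:
  acquisition_ms: 0
  buffer_ms: 10
  compute_ms: 2.05
  transport_ms: 0.21
  actuator_rise_ms: 0.74
policy:
  phase_tolerance: 0.3
  pulse_width_ms: 5
  amplitude_gate: 0
spikes:
  base_rate: 8
  locking_concentration: 2
  preferred_phase: 0
  evoked_probability: 0.5
  evoked_latency_ms: 3
motion:
  frame_rate: 120
  baseline_speed: 20
  smoothness: 0.5
  condition_speed_multipliers:
    no_stim: 1.0
    peak: 0.93
    trough: 1.30
epochs:
  duration_s: 30
  blocks: 2
  conditions: [no_stim, peak, trough]
analysis:
  psd_segment_s: 2
  sfc_window_s: 5
  sfc_frequencies: [4, 20]
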