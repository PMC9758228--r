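Package: phasestim
Title: Simulation and Analysis of Closed-Loop Phase-Targeted Neural Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for simulating and evaluating phase-adaptive closed-loop
    stimulation of low-frequency neural oscillations. Estimates the
    instantaneous phase of a target band in local field potentials with a
    complex Morlet wavelet, predicts phase forward across a modeled hardware
    latency budget, issues phase-targeted pulse commands, and provides the
    offline analytics used to evaluate such systems: circular phase-accuracy
    statistics, Welch power spectra and band power, spike-field coherence
    with explicit handling of indeterminate values, head-movement speed, and
    nonparametric condition contrasts. A synthetic-data module generates
    oscillatory field potentials embedded in 1/f background noise,
    phase-locked and stimulus-evoked spike trains, and smooth head
    trajectories so the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
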