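Package: somnoscope
Title: Mouse Polysomnography Simulation and Sleep EEG Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for rodent sleep research: a semi-Markov simulator of
    scored mouse polysomnography (vigilance-state hypnograms on a 4-second
    epoch grid, two-process homeostatic delta dynamics, state-gated
    synthetic EEG/EMG signals, cataplexy generation), together with the
    analytics applied to such recordings: bout and fragmentation
    statistics, REM-sleep latency, state time-courses, per-epoch power
    spectra (0-90 Hz at 0.25 Hz), state-weighted baseline normalization,
    percentile band-power time-courses across sleep deprivation and
    recovery, theta-dominated-wakefulness classification, and EMG/EEG
    based cataplexy detection. Includes minimal European Data Format (EDF)
    input/output and a deterministic end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
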