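Package: spindev
Title: Spindle-Band Oscillation Detection and Developmental Trajectory
    Analysis for Neonatal LFP and EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterization of spindle-band (8-25 Hz)
    oscillations in neonatal rodent local field potential and human EEG
    recordings, together with the surrounding analysis pipeline:
    EMG-based sleep/wake state scoring, Gabor-wavelet spectral analysis
    with AR(1) whitening, oscillatory-epoch continuity, amplitude-amplitude
    cross-frequency comodulograms, multi-unit spiking statistics
    (autocorrelogram confidence intervals, event-triggered rates,
    spindle-phase locking), and bootstrap localization of interior extrema
    of developmental feature trajectories selected by leave-one-out
    cross-validation. A synthetic-data module generates ground-truthed
    LFP/EEG, EMG, spike trains and multi-animal age cohorts so that every
    stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    MASS,
    rpart,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
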