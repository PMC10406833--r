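Package: pingmap
Title: Decoding the Statistically Learned Spatial Priority Map from
    Ping-Evoked EEG Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A complete, simulation-driven analysis pipeline for visual-search
    statistical-learning experiments in which task-irrelevant high-contrast
    visual impulses ("pings") are used to reveal a latent attentional priority
    map from multichannel EEG. Provides a synthetic-data generator for the
    full experiment (biased/neutral block schedules with a cycling
    high-probability target location, reaction times, 64-channel epochs with
    ping-gated class-specific evoked patterns, and gaze traces with
    controllable confounds), behavioral cleaning and condition contrasts,
    EEG preprocessing (earlobe re-referencing, FIR filtering, adaptive
    z-score EMG rejection with iterative spherical-spline repair, gaze- and
    EOG-based trial exclusion), gaze density maps and towardness curves,
    time-resolved multiclass linear-discriminant decoding scored by AUC with
    pseudo-trial averaging and per-fold PCA, cluster-based sign-flip
    permutation statistics in one and two dimensions, and lateralized ERP
    waveforms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    signal,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
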