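Package: eegflow
Title: EEG Engagement Indices, Flow-Scale Labeling and Difficulty Calibration for Cognitive Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for EEG-based engagement monitoring during
    computerised cognitive gameplay. Calibrates per-player game difficulty from
    in-game metrics with a weighted Performance Index, scores the 14-item flow
    state scale into high/low engagement labels, band-pass filters and epochs
    multi-channel EEG, estimates theta/alpha/beta band powers by multitaper
    spectral estimation and derives the classical engagement indices
    beta/(theta+alpha), beta/alpha and 1/alpha, computes an SNR-based per-channel
    signal quality index, runs Friedman tests with Dunn-Bonferroni post hoc
    comparisons across difficulty levels, and evaluates random-forest and
    support-vector-machine classifiers of high versus low engagement in
    within-subject and cross-subject designs. Includes a synthetic cohort
    generator (oscillations over 1/f noise, gameplay metrics, flow responses)
    so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    randomForest,
    jsonlite,
    tibble,
    dplyr,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
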