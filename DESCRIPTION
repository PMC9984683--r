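Package: qeegtbi
Title: Quantitative EEG Outcome Prediction for Traumatic Brain Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for early-EEG prognostication in moderate-to-severe
    traumatic brain injury at the intensive care unit. Provides multichannel
    EEG preprocessing (zero-phase Butterworth band-pass filtering, common
    average re-referencing, threshold-based artifact masking, flat-channel
    detection, segmentation around clinical timepoints), extraction of
    sixteen quantitative EEG feature families (band powers, alpha/delta
    ratio, spectral edge frequency, band-power variability, brain symmetry
    index, mean magnitude-squared coherence, spectral Shannon entropy,
    amplitude regularity, aperiodic 1/f fit, detrended fluctuation analysis
    of amplitude envelopes and Kuramoto phase dynamics, and broken
    detailed-balance measures), and cross-validated random-forest outcome
    classification with backward feature elimination, McNemar model
    comparison and an IMPACT-style logistic baseline. A synthetic ICU-EEG
    cohort generator with controllable spectral, asymmetry, variability and
    long-range-correlation structure supports testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    randomForest,
    pROC,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
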