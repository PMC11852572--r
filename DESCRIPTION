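Package: coldperf
Title: Detecting Cold-Exposure Cognitive Performance Deterioration from
    Wearable Electrodermal and Cardiac Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Feature extraction and evaluation pipeline for detecting
    deterioration of cognitive task performance during cold exposure from
    wearable electrodermal activity (EDA) and electrocardiogram (ECG)
    recordings. Implements convex phasic/tonic EDA decomposition, the
    time-varying sympathetic index (variable-frequency complex demodulation
    with a Hilbert envelope), skin-conductance-response counting,
    heart-rate-variability features (HR, RMSSD, high-frequency power) with
    R-R interval cleaning, area-weighted skin and mean body temperature,
    a baseline-percentile performance-deterioration labeling rule,
    effect-size statistics, and leave-one-subject-out machine-learning
    evaluation with minority oversampling and geometric-mean model
    selection. A synthetic-cohort generator with known ground truth makes
    every stage testable without access to raw study recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    splines,
    e1071,
    ranger,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
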