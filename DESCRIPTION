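Package: infantmotor
Title: Infant Motor Ability Analytics for Multi-Sensor Wearable Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of infant movement recordings from a
    four-sensor limb-worn inertial wearable. Provides a synthetic-data
    generator for posture/movement/carrying state sequences and realistic
    accelerometer/gyroscope signals, signal preprocessing (timestamp
    regularization to 52 Hz, gyroscope bias removal, median filtering,
    overlapping 2.3-s framing), multi-rater annotation handling with
    compounded confusion matrices, Fleiss' kappa and iterative annotation
    refinement, a dual-track convolutional sequence classifier for posture
    and movement plus a binary active-carrying detector, contrastive
    predictive coding (InfoNCE) pretraining, recording-level motor-ability
    distributions, an age-normative Gaussian-likelihood maturity score
    (BIMS) with leave-one-subject-out evaluation and recording-length
    robustness analysis, and the accompanying agreement and evaluation
    statistics (Bland-Altman, monthly-change slopes, correlation tests, and
    a battery of dependent overlapping-correlation comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
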