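Package: speckledrink
Title: Remote Alcohol-Consumption Sensing from Laser Speckle Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for camera-based detection of alcohol
    consumption from defocused laser speckle videos. Tracks the lateral
    displacement of the speckle pattern by frequency-domain cross-correlation
    of consecutive frames with optional subpixel refinement, slices the
    displacement time series into overlapping chunks, extracts a fixed
    registry of time-series features per channel, filters features by
    rank-based hypothesis tests against the target labels, and trains a
    gradient-boosted decision-tree classifier under several label-merging
    schemes with seeded random hyperparameter search. Includes a synthetic
    speckle-video simulator with a heartbeat-driven tilt waveform (0.5-3 Hz
    band, heart-rate variability, sub-0.5 Hz drift and sensor noise) so the
    whole method is testable without human-subject recordings, plus confusion
    matrix, accuracy/precision/sensitivity/specificity/F1 and ROC/AUC
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    tools,
    digest,
    png,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
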