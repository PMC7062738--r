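Package: doceeg
Title: Resting-State and Event-Related EEG Markers of Consciousness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies conscious state from multichannel EEG in disorders of
    consciousness. Implements an automated artifact-rejection cascade, seventeen
    resting-state markers (band powers, spectral summaries, permutation entropy,
    Lempel-Ziv complexity, weighted symbolic mutual information), a linear-SVM
    multivariate predictor of minimally conscious state, oddball ERP contrasts
    with temporal-generalization decoding, two-step cluster-based permutation
    statistics over channels, channel pairs, space-time and decoding matrices,
    and a voxelwise electric-field correlation test. A seeded synthetic-cohort
    generator emulates responder/non-responder study designs for calibration
    and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    broom
Config/testthat/edition: 3
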