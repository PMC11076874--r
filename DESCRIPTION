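Package: spindlecnn
Title: Sleep Spindle Classification with a 1D Convolutional Neural Network and Transfer Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sleep spindles -- 11-16 Hz oscillatory EEG bursts of
    roughly 0.5-2 s that mark NREM stage-2 sleep -- in polysomnography
    recordings using a five-block one-dimensional convolutional neural
    network trained on balanced 3 s windows. Provides the full pipeline:
    a synthetic polysomnography generator with normal and insomnia-like
    spindle regimes, EDF and CSV signal input/output, the preprocessing
    chain (polyphase downsampling to 100 Hz, zero-phase Hamming-window
    FIR band-pass 0.3-30 Hz, z-score normalization), balanced window
    extraction centred on annotated spindle midpoints, subject-grouped
    five-fold cross-validated training with an AdamW optimizer and a
    stepped learning-rate schedule, a five-metric evaluation suite
    (accuracy, recall, precision, F1, AUC), and two transfer-learning
    modes that freeze either all five or the first four convolutional
    blocks when adapting to a domain-shifted cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
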