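Package: micnn
Title: Generalizable and Discriminative Training for Motor-Imagery EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Subject-dependent motor-imagery EEG classification with a compact
    temporal/depthwise/separable convolutional network supervised by a combined
    objective of label-smoothed cross-entropy and center loss. Includes a
    canonical labeled-trial container with archive I/O, cue-window epoching and
    channel selection; a synthetic motor-imagery session generator with
    controllable event-related-desynchronization strength so the whole pipeline
    is testable without external recordings; a seeded mini-batch training loop
    with per-epoch learning-curve logging; an ablation harness over the loss
    weights; and evaluation utilities (accuracy, paired t-tests, PCA projection
    of penultimate features, class-dispersion summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    ggplot2,
    generics,
    rlang
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
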