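Package: mcafnet
Title: Multi-Channel Cross-Attention Sleep Stage Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Five-class sleep stage classification (W, N1, N2, N3, REM) from
    multi-channel 30 s polysomnography epochs. Raw EEG/EOG signals are
    converted to standardized log-power spectrograms, per-channel temporal
    features are extracted with a lightweight depthwise-separable temporal
    convolution, and channels are fused with a dynamically gated multi-head
    cross-channel attention mechanism before a two-layer softmax classifier.
    Includes the full training protocol (AdamW, early stopping, subject-wise
    k-fold cross-validation), evaluation metrics (confusion matrices,
    Cohen's kappa, macro-F1, sensitivity/specificity, hypnograms,
    attention-weight aggregation), a seeded generator of stage-conditioned
    synthetic polysomnography, and EDF import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
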