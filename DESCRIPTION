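Package: ctgaug
Title: GAN-Based Augmentation and Classification for Imbalanced Cardiotocography Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and classification of fetal-distress anomalies in severely
    imbalanced cardiotocography (CTG) and maternal-clinical tabular data. Per-class
    boundary-equilibrium generative adversarial networks (BEGAN) with a
    convergence-measure stopping rule synthesize minority-class records; an
    autoencoder trained on the expanded data supplies a frozen feature extractor;
    small dense, one-dimensional convolutional and LSTM heads perform binary and
    three-class classification. Includes a synthetic dataset generator emulating the
    reassuring/non-reassuring CTG labeling rule, an FHR-trace preprocessing pipeline
    (outlier trimming, prefix-median imputation, decentralization, zero-mean
    standardization), and an evaluation suite with per-class metrics, ROC,
    repeated-run statistics, exact McNemar tests and bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
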