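Package: vqsvdd
Title: Vector-Quantized Autoencoder with Deep SVDD for Slice-Based Anomaly
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: One-class anomaly detection for stacks of 2D grayscale slice
    images (e.g. chest CT screening volumes). A vector-quantized autoencoder
    learns to reconstruct normal anatomy through a discrete codebook while an
    inner encoder maps latent variables into a minimal hypersphere (deep
    SVDD); slices are scored by the sum of squared reconstruction error and
    squared distance to the hypersphere center, and examinees by the maximum
    slice score. Includes a three-step training protocol with MS-SSIM based
    reconstruction losses, a plain convolutional VAE baseline, a seeded
    synthetic chest-phantom generator for benchmarking, sixfold
    cross-validation utilities, and ROC/Youden-index screening evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pROC,
    png,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
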