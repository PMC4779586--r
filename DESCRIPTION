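Package: gaitcs
Title: Compressed Sensing of Wearable Accelerometer Data for Gait Telemonitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for low-energy telemonitoring of human gait from body-worn
    tri-axial accelerometers via compressed sensing. Constructs sparse binary
    measurement matrices with a minimal number of nonzero entries per column
    (plus dense Gaussian and Bernoulli references), reconstructs the non-sparse
    acceleration signal by block sparse Bayesian learning with bound
    optimization (BSBL-BO) exploiting block partitions and intra-block
    correlation, and provides classic sparse-recovery baselines (orthogonal
    matching pursuit, subspace pursuit, smoothed-l0, basis pursuit) operating
    in an orthonormal discrete cosine basis. Includes reconstruction-quality
    criteria (compression ratio, NMSE, SNR, Pearson correlation), windowed
    statistical gait features with multiclass classification-evaluation
    metrics and cross-validation protocols, synthetic generators for
    block-sparse and gait-like signals, readers and writers for plain-text
    recordings and MATLAB container files, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    nnet,
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
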