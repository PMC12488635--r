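Package: phageMoE
Title: Gated Mixture-of-Experts Fusion for Phage-Host Interaction Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts phage-host interactions by fusing interpretable
    statistical protein descriptors (amino acid composition, atomic
    composition, molecular weight) with two high-dimensional protein
    embedding streams through a sample-specific gating network
    (mixture-of-experts). A small 1D convolutional network is trained
    jointly with the gate by cross-entropy on labelled phage-host pairs
    derived from a continuous infection-score matrix. Includes seeded
    synthetic fixture generators, class-imbalance resampling
    (over/under-sampling), stratified cross-validation, threshold and
    threshold-free evaluation metrics (accuracy, precision, sensitivity,
    specificity, F1, AUROC, AUPR), and gate-weight interpretability
    exports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pheatmap,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
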