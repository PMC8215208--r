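Package: hicnet
Title: Hierarchical Coarse-to-Fine Multi-Label Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Taxonomy-guided hierarchical deep learning for multi-task,
    multi-label image classification. Provides a disease-taxonomy label
    algebra (upward label expansion, consistency checking), a compact
    convolutional backbone with per-level branch heads wired coarse-to-fine,
    a multi-level focal-loss objective for imbalanced multi-label data, a
    freeze-then-unfreeze staged fine-tuning schedule, cross-validated
    ROC/AUC and confusion-matrix evaluation, and Grad-CAM saliency maps
    with a quantitative localization score. Includes a seeded synthetic
    image generator with a two-level class hierarchy and known lesion
    geometry so the whole pipeline can be exercised end-to-end without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
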