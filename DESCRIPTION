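Package: stripfuse
Title: Strip-Pooling Attention Networks for Brain Tumour MRI Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A trainable convolutional network for four-class brain tumour
    MRI classification (glioma, meningioma, pituitary adenoma, no tumour)
    built from a shallow VGG-style spatial-block backbone and a deep
    residual-block backbone, fused across scales through strip-pooling
    attention heads. Includes the full preprocessing chain (resizing,
    grayscale conversion, unsharp masking, Sobel edge enhancement,
    training-time augmentation), a deterministic stratified 7:3 dataset
    splitter with global-ID deduplication, an AdamW training loop with
    best-validation checkpointing, multi-class evaluation metrics
    (confusion matrix, macro precision/recall/F1, per-class and
    micro-average ROC/AUC), a seeded four-class phantom generator so the
    whole pipeline can be exercised without any external download, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
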