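Package: ctgvision
Title: Digitization and Attention-Based Classification of Cardiotocography
    Chart Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for objective interpretation of cardiotocography (CTG)
    report images. Synthesizes gridded fetal-heart-rate (FHR) and
    uterine-contraction (UC) chart pages with exact ground truth, digitizes
    chart images back into physical-unit time series (grid-removal
    binarization, pixel-to-value coordinate mapping, resampling and
    chronological splicing), classifies 20-minute recordings as Reassuring
    versus Non-Reassuring with a CBAM-enhanced EfficientNet-B0 implemented
    from first principles (mobile inverted bottleneck blocks,
    squeeze-and-excitation gating, channel and spatial attention), and
    evaluates classifiers with confusion-matrix metrics, ROC/PR analysis,
    stratified k-fold cross-validation and staged t-SNE embeddings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
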