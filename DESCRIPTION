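Package: leukotype
Title: Two-Stage Classification of Atypical White Blood Cells with
    Autoencoder-Based Augmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for morphological classification of single-cell white
    blood cell (WBC) images from peripheral blood smears, aimed at the
    atypical and immature cells seen in acute myeloid leukemia. Implements
    a geometric-transformation plus deep convolutional autoencoder
    (GT-DCAE) augmentation scheme for rebalancing rare WBC subtypes, a
    latent-representation feature extractor, and a two-stage convolutional
    classifier (typical-versus-atypical gate followed by an eight-way
    atypical subtype model), together with a synthetic single-cell image
    generator, stratified manifest handling, and the full evaluation stack
    (confusion matrices, precision/sensitivity/specificity, F-scores,
    one-vs-rest ROC/AUC). The convolutional networks are implemented in
    the package itself via 'RcppArmadillo' kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
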