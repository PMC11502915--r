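Package: cxrcad
Title: Computer-Aided Detection and Reader-Study Evaluation for Chest Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale computer-aided detection (CAD) pipeline for chest
    radiographs and its full evaluation machinery. Implements the three-stage
    image pipeline (black-padding crop and aspect-preserving standardization;
    a convolutional case-level analysis network with a beta-binomial
    k-of-n annotator likelihood and a pixel-probability localization branch;
    operating-point calibration, binary category determinations and
    bounding-box extraction), together with standalone performance statistics
    (per-category and micro-averaged ROC AUC, sensitivity, specificity,
    case-level bootstrap confidence intervals, summed-box intersection over
    union) and multi-reader multi-case (MRMC) reader-study statistics
    (crossover design generation, Dorfman-Berbaum-Metz jackknife
    pseudovalue analysis, DeLong tests, miss-rate reduction, read-time
    analysis). A synthetic phantom-case generator with a simulated labeler
    panel makes every component testable without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    png,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
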