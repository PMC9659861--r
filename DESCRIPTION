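Package: mcvit
Title: Multi-Path Cross-Scale Vision Transformer for Histopathology Slide Typing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-stage transformer pipeline for thymoma
    histopathology whole-slide-image (WSI) typing. The first stage is a
    cross attentive scale-aware transformer (CAST) that classifies
    co-registered multi-scale patch triplets (10x/20x/40x) into ten
    patch-level pathological-information classes, fusing its three branches
    (global, local, and aggregation) with a cross-correlation attention
    module (CAM). The second stage is a slide-level WSI transformer (WT)
    that encodes each slide as a fixed-size feature matrix of multi-scale
    patch embeddings concatenated with pathological-label priors and
    predicts one of eight thymoma types. Includes a reverse-mode automatic
    differentiation engine with an Armadillo attention kernel, Adam
    training loops, a synthetic multi-scale dataset generator with
    controlled scale-specific class signal, and the full evaluation suite
    (confusion-matrix metrics, one-vs-rest ROC/AUC, Wilson intervals, and
    continuity-corrected McNemar tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    png,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    rpart
Config/testthat/edition: 3
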