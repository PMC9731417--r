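Package: pcgfusion
Title: Heart Sound Classification with Adaptive Empirical Mode Decomposition
    and Fused Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying phonocardiogram (heart sound) recordings.
    Implements empirical mode decomposition (EMD) with two adaptive rules for
    screening intrinsic mode functions before reconstruction: a joint
    correlation-coefficient and root-mean-square-error threshold, and an
    adaptive Hausdorff-distance threshold over the first seven decomposition
    layers. From the reconstructed signal a 40-dimensional fused feature
    vector is extracted (time-domain statistics, spectral and
    instantaneous-frequency descriptors, entropy measures, and four cardiac
    reserve times obtained by envelope-based S1/S2 segmentation). Features can
    be ranked by six selection algorithms (mRMR, KCCA-gated mRMR, quadratic
    programming feature selection, maximal information coefficient, tree
    importance, and recursive feature elimination with cross-validation) and
    evaluated by incremental top-k stratified cross-validation with random
    forest, k-nearest-neighbour, or decision-tree classifiers. A synthetic
    phonocardiogram generator with ground-truth segmentation supports fully
    reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    class,
    jsonlite,
    randomForest,
    Rcpp,
    rpart,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
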