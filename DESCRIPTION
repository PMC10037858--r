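Package: grnstack
Title: Stacked Ensemble Inference of Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-level stacking pipeline for gene regulatory network inference.
    Level-1 methods (correlation, partial correlation, lagged correlation,
    mutual information, tree-based importance, ODE ridge regression, or any
    externally produced ranked-edge file) score every candidate transcription
    factor to target edge from expression data. A level-2 ensemble classifier
    (Gaussian Naive Bayes by default, after a positive-kurtosis input filter)
    learns from gold-standard edges of training regulators and predicts edges
    for held-out regulators. Includes a DREAM-style ODE time-series expression
    simulator with known ground truth, AUPRC-ratio evaluation against a random
    predictor, repeated TF-disjoint split benchmarking, and a non-parametric
    paired sign-flip resampling test.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    e1071,
    ranger,
    rlang,
    rpart,
    stats,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
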