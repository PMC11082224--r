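Package: activetest
Title: Active Testing of Pre-Trained Classifiers with Improved Weighted Estimators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates pre-trained classification models when outcome labels
    are expensive, by sequentially selecting informative subsets of an
    unlabeled test pool for labeling (active testing). Implements the
    levelled unbiased risk (LUR) estimator and two actively improved
    estimators, AILUR and AIIPW, which replace true Poisson sampling weights
    with Nadaraya-Watson kernel-smoothed estimates of the selection and
    cumulative inclusion probabilities. Sampling probabilities are driven by
    expected cross-entropy loss and can be sharpened by a one-parameter
    recalibration of the evaluated model fitted through a weighted
    estimating equation. Covers loss metrics (cross-entropy, squared error)
    and ratio-form predictive accuracy metrics (TPR, FPR, PPV, NPV, F1) at a
    risk cutoff, plus weighted AUC and AUPRC, together with a simulation
    harness reporting RMSE curves and relative efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
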