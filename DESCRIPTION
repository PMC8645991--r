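Package: mcpc
Title: Multiple Connection Pattern Combination for Brain Network Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates three brain-connection patterns from region-of-interest
    (ROI) time series -- Pearson correlation, sparse-representation partial
    correlation, and bivariate Granger causality mapping -- and fuses them with
    a multi-kernel support vector machine whose per-pattern kernel weights are
    learned on the probability simplex (SimpleMKL). Includes nested
    leave-one-out cross-validation with per-fold feature selection, ROC/AUC and
    DeLong comparison of correlated AUCs, group-level hub identification,
    consensus-connection extraction across cross-validation folds with AAL
    atlas annotation, and a synthetic two-group VAR(1) cohort generator with
    known contemporaneous and lagged connectivity differences for end-to-end
    validation without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    glmnet,
    optparse
Config/testthat/edition: 3
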