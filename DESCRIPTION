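Package: autosig
Title: Automated Biosignature Discovery with Bias-Corrected Performance Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated machine-learning engine for binary-outcome,
    high-dimensional biomedical tables. Builds a space of full analysis
    pipelines (imputation, encoding, standardization, feature selection,
    classification), evaluates each pipeline as an indivisible unit under a
    stratified, repeated, possibly incomplete K-fold cross-validation
    protocol, and corrects the winning pipeline's performance estimate for
    the winner's curse by bootstrapping the selection step on the pooled
    out-of-sample prediction matrix (BBC-CV). Feature selection can return
    multiple statistically equivalent minimal signatures (SES-style), and
    post-analysis tools provide threshold-dependent metrics with bootstrap
    confidence intervals, permutation-based variable importance, individual
    conditional expectation curves, and permutation tests for comparing
    analysis runs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    rpart,
    ranger,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
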