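# Independent oracles used across tests. These stay deliberately naive:
# exhaustive enumeration and brute-force loops, never the package's own
# code paths.

# AUC by exhaustive positive-negative pair counting, ties worth 1/2
pair_count_auc <- function(pred, labels, positive) {
  pos <- pred[labels == positive]
  neg <- pred[labels != positive]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(pos) * length(neg))
}

# exact two-tailed p-value of the exchange/sign-flip median test by
# enumerating all 2^n sign patterns (feasible for n <= 12)
exact_signflip_p <- function(d) {
  n <- length(d)
  M <- stats::median(d)
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0, -1, 1)
    if (abs(stats::median(signs * d)) >= abs(M)) hits <- hits + 1L
  }
  hits / 2^n
}

# plain stratified K-fold CV, coded independently of run_gcv: its own loop
# over folds, fitting each configuration's stages directly
reference_kfold_cv <- function(d, configs, K, fold_ids) {
  preds <- matrix(NA_real_, n_samples(d), length(configs))
  for (k in seq_len(K)) {
    te <- which(fold_ids == k)
    tr <- which(fold_ids != k)
    pre <- fit_preprocess(d$values[tr, , drop = FALSE])
    Xte <- apply_preprocess(pre$chain, d$values[te, , drop = FALSE])
    for (ci in seq_along(configs)) {
      conf <- configs[[ci]]
      feats <- switch(conf$selector$kind,
        none = colnames(pre$train),
        ses = primary_signature(ses_select(
          pre$train, d$outcome[tr], alpha = conf$selector$params$alpha,
          maxk = conf$selector$params$maxk)),
        lasso = primary_signature(lasso_select(
          pre$train, d$outcome[tr], penalty = conf$selector$params$penalty)))
      clf <- fit_classifier(conf$classifier$family, conf$classifier$hyper,
                            pre$train[, feats, drop = FALSE], d$outcome[tr],
                            d$positive, seed = 1L)
      preds[te, ci] <- predict_proba(clf, Xte[, feats, drop = FALSE])
    }
  }
  preds
}
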