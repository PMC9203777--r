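# AUC, BBC-CV correction, threshold metrics, final-model production.

test_that("auc matches exhaustive pair counting with tie halving", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), positive = "1"), 0.75)
  expect_equal(auc(c(0, 0, 1, 1), c("n", "n", "p", "p"), positive = "p"), 1)
  expect_equal(auc(rep(0.5, 10), rep(c("n", "p"), 5), positive = "p"), 0.5)
  set.seed(3)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    labels <- factor(c("n", "p", sample(c("n", "p"), n - 2, replace = TRUE)))
    pred <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    expect_equal(auc(pred, labels, positive = "p"),
                 pair_count_auc(pred, labels, "p"), tolerance = 1e-12)
  }
})

make_oos <- function(P, labels, sample_idx = seq_len(nrow(P))) {
  colnames(P) <- sprintf("c%03d", seq_len(ncol(P)))
  structure(list(predictions = P, labels = factor(labels), positive = "pos",
                 sample_idx = sample_idx,
                 repeat_idx = rep(1L, nrow(P)),
                 config_ids = colnames(P),
                 dropped = rep(FALSE, ncol(P)), failed = rep(FALSE, ncol(P)),
                 pooled_auc = apply(P, 2, auc, labels = labels, positive = "pos"),
                 n_features = rep(NA_real_, ncol(P)),
                 completed_repeats = 1L),
            class = "autosig_oos")
}

test_that("with a single configuration the correction is a no-op up to noise", {
  set.seed(5)
  y <- rep(c("neg", "pos"), 100)
  P <- matrix(ifelse(y == "pos", 0.7, 0.3) + rnorm(200, sd = 0.2), ncol = 1)
  oos <- make_oos(P, y)
  cb <- bbc_correct(oos, B = 500, seed = 9)
  expect_lt(abs(cb$point - cb$unadjusted), 0.01)
  expect_lte(cb$ci_low, cb$point)
  expect_gte(cb$ci_high, cb$point)
})

test_that("a dominant perfect configuration stays near 1 after correction", {
  set.seed(6)
  y <- rep(c("neg", "pos"), 50)
  P <- cbind(ifelse(y == "pos", 0.9, 0.1), matrix(runif(100 * 20), 100, 20))
  cb <- bbc_correct(make_oos(P, y), B = 300, seed = 2)
  expect_equal(cb$winner_id, "c001")
  expect_gt(cb$point, 0.95)
})

test_that("the correction removes the winner's curse on null matrices", {
  set.seed(7)
  res <- t(vapply(1:10, function(i) {
    y <- rep(c("neg", "pos"), 50)
    P <- matrix(runif(100 * 100), 100, 100)   # 100 random-guess configurations
    cb <- bbc_correct(make_oos(P, y), B = 200, seed = i)
    c(cb$unadjusted, cb$point)
  }, numeric(2)))
  expect_gt(mean(res[, 1]), 0.55)             # selection optimism is real
  expect_gt(mean(res[, 2]), 0.45)             # and the correction removes it
  expect_lt(mean(res[, 2]), 0.55)
})

test_that("correction is invariant to row and column order", {
  set.seed(8)
  y <- rep(c("neg", "pos"), 40)
  P <- matrix(runif(80 * 5), 80, 5)
  P[, 3] <- ifelse(y == "pos", 0.8, 0.2) + rnorm(80, sd = 0.25)
  base <- bbc_correct(make_oos(P, y), B = 400, seed = 3)
  perm <- sample(80)
  shuffled <- bbc_correct(make_oos(P[perm, ], y[perm], sample_idx = perm), B = 400, seed = 3)
  expect_equal(shuffled$point, base$point, tolerance = 0.03)
  swapped <- bbc_correct(make_oos(P[, c(3, 1, 2, 4, 5)], y), B = 400, seed = 3)
  expect_equal(swapped$winner_id, "c001")     # same winning column, new position
  expect_equal(swapped$point, base$point, tolerance = 0.03)
})

test_that("bbc4rocs places T quantile thresholds and obeys ROC monotonicity", {
  set.seed(9)
  y <- rep(c("neg", "pos"), 100)
  pred <- ifelse(y == "pos", 0.65, 0.35) + rnorm(200, sd = 0.2)
  th <- bbc4rocs(pred, y, positive = "pos", T = 10, B = 200, seed = 4)
  expect_length(th$thresholds, 10)
  expect_equal(th$thresholds,
               quantile(pred, probs = (1:10) / 11, names = FALSE))
  expect_false(is.unsorted(th$thresholds))
  expect_true(all(diff(th$roc$tpr) <= 1e-9))  # TPR non-increasing in t
  expect_true(all(diff(th$roc$fpr) <= 1e-9))
  # a threshold below every prediction calls everything positive
  m <- autosig:::threshold_metrics_at(pred, y == "pos", min(pred) - 1)
  expect_equal(unname(m["sensitivity"]), 1)
  expect_equal(unname(m["specificity"]), 0)
})

test_that("bbc4rocs collapses duplicate thresholds with a warning", {
  y <- rep(c("neg", "pos"), 30)
  pred <- rep(c(0.2, 0.8), 30)
  expect_warning(th <- bbc4rocs(pred, y, positive = "pos", T = 10, B = 50, seed = 1),
                 "duplicate")
  expect_lt(length(th$thresholds), 10)
})

test_that("finalize refits on every sample and predicts in range", {
  fx <- generate_fixture(fixture_spec(n = 60, p = 8, k_informative = 2,
                                      effect_sizes = c(1.5, 1), seed = 12))
  conf <- single_config(selector = list(kind = "lasso",
                                        params = list(penalty = 0.05,
                                                      max_features = 25L),
                                        aggressive = FALSE))
  model <- finalize(fx$dataset, conf, seed = 2)
  expect_equal(model$n_train, 60L)
  pr <- predict(model, fx$dataset)
  expect_length(pr, 60)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_lte(length(model$features), 25)
  # serialization round-trip
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  expect_identical(predict(load_model(path), fx$dataset), pr)
})
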