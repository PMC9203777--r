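# Transforms and classifiers: fit-on-training-only contracts, imputation,
# encoding, standardization, probability outputs.

train_tbl <- function() data.frame(
  num = c(1, NA, 3, 4, 10),
  cat = c("a", "a", "b", NA, "a"),
  const = rep(7, 5),
  stringsAsFactors = FALSE)

test_that("imputation stores the training mean and mode", {
  t <- fit_transform("mean_mode_impute", data.frame(x = c(1, NA, 3)))
  out <- apply_transform(t, data.frame(x = c(NA, 5)))
  expect_equal(out$x, c(2, 5))
  tc <- fit_transform("mean_mode_impute", data.frame(g = c("a", "a", "b")))
  expect_equal(apply_transform(tc, data.frame(g = NA_character_))$g, "a")
  # identity on complete data, and idempotent
  cmpl <- data.frame(x = c(1, 2))
  expect_equal(apply_transform(t, cmpl), cmpl)
  once <- apply_transform(t, data.frame(x = c(NA, 5)))
  expect_equal(apply_transform(t, once), once)
})

test_that("constant columns are removed before standardization", {
  tr <- train_tbl()
  t <- fit_transform("constant_removal", tr)
  out <- apply_transform(t, tr)
  expect_named(out, c("num", "cat"))
  expect_error(fit_transform("standardize", data.frame(x = rep(2, 4))),
               class = "autosig_zero_variance")
})

test_that("standardization uses fit-time statistics only", {
  a <- data.frame(x = c(1, 2, 3, 4))
  b <- data.frame(x = c(10, 20, 30))
  t <- fit_transform("standardize", a)
  za <- apply_transform(t, a)$x
  expect_equal(mean(za), 0, tolerance = 1e-9)
  expect_equal(sd(za), 1, tolerance = 1e-9)
  zb <- apply_transform(t, b)$x
  expect_gt(abs(mean(zb)), 1)  # fold-B mean is far from 0: no re-fitting
})

test_that("one-hot encoding maps unseen levels to all zeros", {
  t <- fit_transform("one_hot", data.frame(g = c("a", "a", "b")))
  enc <- apply_transform(t, data.frame(g = c("b", "c")))
  expect_equal(unname(as.matrix(enc)), rbind(c(0, 1), c(0, 0)))
  expect_named(enc, c("g=a", "g=b"))
})

test_that("transforms reject a schema mismatch", {
  t <- fit_transform("standardize", data.frame(x = c(1, 2, 3)))
  expect_error(apply_transform(t, data.frame(z = 1)), class = "autosig_schema_mismatch")
})

test_that("the baseline classifier predicts the training positive rate", {
  y <- factor(rep(c("case", "control"), c(7, 3)))
  X <- matrix(rnorm(10), 10, 1)
  clf <- fit_classifier("baseline_majority", list(), X, y, positive = "case")
  expect_equal(predict_proba(clf, X), rep(0.7, 10))
})

test_that("heavy ridge penalty shrinks predictions toward the class prior", {
  set.seed(2)
  X <- matrix(rnorm(200), 100, 2)
  y <- factor(ifelse(X[, 1] + rnorm(100) > 0, "pos", "neg"))
  clf <- fit_classifier("ridge_logistic", list(lambda = 1e6), X, y, positive = "pos")
  pr <- predict_proba(clf, X)
  expect_lt(diff(range(pr)), 0.01)
  expect_equal(mean(pr), mean(y == "pos"), tolerance = 0.02)
})

test_that("a linear SVM separates separable 1-D data perfectly", {
  X <- matrix(c(-3, -2.5, -2, 2, 2.5, 3), 6, 1)
  y <- factor(rep(c("neg", "pos"), each = 3))
  clf <- fit_classifier("svm_linear", list(cost = 10), X, y, positive = "pos")
  pr <- predict_proba(clf, X)
  expect_true(all(pr[y == "pos"] > 0.5))
  expect_true(all(pr[y == "neg"] < 0.5))
})

test_that("probabilities stay in [0,1] and follow a monotone single coefficient", {
  set.seed(7)
  X <- matrix(rnorm(80), 80, 1, dimnames = list(NULL, "x"))
  y <- factor(ifelse(X[, 1] + rnorm(80, sd = 0.5) > 0, "pos", "neg"))
  for (fam in c("decision_tree", "ridge_logistic", "random_forest",
                "svm_linear", "svm_rbf")) {
    clf <- fit_classifier(fam, list(lambda = 0.1, cost = 1, gamma = 0.5,
                                    min_leaf = 3, num_trees = 50),
                          X, y, positive = "pos", seed = 3)
    pr <- predict_proba(clf, X)
    expect_length(pr, 80)
    expect_true(all(pr >= 0 & pr <= 1), info = fam)
  }
  ridge <- fit_classifier("ridge_logistic", list(lambda = 0.1), X, y, positive = "pos")
  grid <- matrix(seq(-2, 2, length.out = 11), ncol = 1, dimnames = list(NULL, "x"))
  expect_false(is.unsorted(predict_proba(ridge, grid)))
})

test_that("single-class training data falls back to the baseline with a warning", {
  X <- matrix(rnorm(10), 10, 1)
  y <- factor(rep("pos", 10), levels = c("neg", "pos"))
  expect_warning(clf <- fit_classifier("ridge_logistic", list(lambda = 1), X, y, "pos"),
                 "single-class")
  expect_equal(clf$family, "baseline_majority")
  expect_equal(predict_proba(clf, X), rep(1, 10))
})

test_that("stochastic classifiers are deterministic given a seed", {
  set.seed(10)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- factor(ifelse(X[, 1] > 0, "pos", "neg"))
  f1 <- fit_classifier("random_forest", list(num_trees = 50), X, y, "pos", seed = 5)
  f2 <- fit_classifier("random_forest", list(num_trees = 50), X, y, "pos", seed = 5)
  expect_identical(predict_proba(f1, X), predict_proba(f2, X))
})

test_that("a full pipeline on null high-dimensional data shows no leakage", {
  # selection inside every training fold: pooled out-of-sample AUC stays at
  # chance on average, unlike the select-then-cross-validate mistake
  aucs <- vapply(1:20, function(s) {
    fx <- generate_fixture(fixture_spec(n = 60, p = 150, k_informative = 0, seed = s))
    conf <- single_config(selector = list(kind = "lasso",
                                          params = list(penalty = 0.05,
                                                        max_features = 25L),
                                          aggressive = FALSE))
    plan <- plan_protocol(compute_meta_features(fx$dataset), R = 1, K = 5,
                          seed = s)
    run_gcv(fx$dataset, list(conf), plan)$pooled_auc[1]
  }, numeric(1))
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})
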