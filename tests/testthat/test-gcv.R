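# Protocol planning, fold construction, the CV engine, and the search
# heuristics.

test_that("protocol defaults emulate the named special cases", {
  meta <- function(n, rarest) structure(list(n = n, rarest_class = rarest),
                                        class = "autosig_meta")
  big <- plan_protocol(meta(5000, 2000))           # 10% holdout
  expect_equal(c(big$R, big$K, big$N), c(1L, 10L, 1L))
  mid <- plan_protocol(meta(300, 120))             # repeated 10-fold CV
  expect_equal(c(mid$R, mid$K, mid$N), c(5L, 10L, 10L))
  tiny <- plan_protocol(meta(50, 25))
  expect_equal(c(tiny$R, tiny$K, tiny$N), c(10L, 20L, 20L))
  rare <- plan_protocol(meta(60, 4))               # K capped by rarest class
  expect_lte(rare$K, 4L)
  expect_error(plan_protocol(meta(60, 1)), class = "autosig_class_too_small")
  std <- plan_protocol(meta(300, 120), R = 1, K = 10, N = 10)  # plain 10-fold
  expect_equal(c(std$R, std$K, std$N), c(1L, 10L, 10L))
})

test_that("folds are stratified within one sample of proportionality", {
  set.seed(5)
  for (i in 1:50) {
    n1 <- sample(10:40, 1); n0 <- sample(10:40, 1)
    K <- sample(2:min(10, n1, n0), 1)
    d <- new_dataset(data.frame(x = rnorm(n1 + n0)),
                     rep(c("a", "b"), c(n0, n1)))
    f <- build_folds(d, K, seed = i)
    for (lv in c("a", "b")) {
      per_fold <- table(factor(f[d$outcome == lv], levels = 1:K))
      expect_lte(max(per_fold) - min(per_fold), 1)
      expect_gte(min(per_fold), 1)
    }
  }
})

test_that("grouped samples occupy exactly one fold", {
  fx <- generate_fixture(fixture_spec(n = 60, p = 3, minority_fraction = 0.5, seed = 3))
  d <- fx$dataset
  d$group_ids <- as.character(rep(1:20, each = 3))
  for (seed in 1:10) {
    f <- build_folds(d, 4, seed = seed)
    per_group <- tapply(f, d$group_ids, function(v) length(unique(v)))
    expect_true(all(per_group == 1))
  }
})

test_that("complete single-repeat GCV predicts every sample exactly once", {
  fx <- generate_fixture(fixture_spec(n = 40, p = 5, k_informative = 1,
                                      effect_sizes = 1, seed = 6))
  plan <- plan_protocol(compute_meta_features(fx$dataset), R = 1, K = 5, seed = 2)
  oos <- run_gcv(fx$dataset, tiny_space(), plan)
  expect_equal(sort(oos$sample_idx), 1:40)
  expect_false(anyNA(oos$predictions))
  expect_equal(oos$completed_repeats, 1L)
})

test_that("incomplete CV holds out exactly the first N folds per repeat", {
  fx <- generate_fixture(fixture_spec(n = 50, p = 4, k_informative = 1, seed = 7))
  plan <- plan_protocol(compute_meta_features(fx$dataset), R = 2, K = 5, N = 2, seed = 3)
  oos <- run_gcv(fx$dataset, tiny_space()[1:2], plan)
  expect_equal(oos$completed_repeats, 2L)
  for (r in 1:2) {
    rows <- oos$repeat_idx == r
    folds <- build_folds(fx$dataset, 5, autosig:::derive_seed(3, r - 1))
    expect_setequal(oos$sample_idx[rows], which(folds <= 2))
    expect_equal(anyDuplicated(oos$sample_idx[rows]), 0L)
  }
})

test_that("GCV with R=1, N=K reduces to plain stratified K-fold CV", {
  fx <- generate_fixture(fixture_spec(n = 40, p = 6, k_informative = 2,
                                      effect_sizes = c(1.5, 1), seed = 8))
  d <- fx$dataset
  plan <- plan_protocol(compute_meta_features(d), R = 1, K = 4, seed = 11)
  oos <- run_gcv(d, tiny_space(), plan)
  fold_ids <- build_folds(d, 4, autosig:::derive_seed(11, 0))
  ref <- reference_kfold_cv(d, tiny_space(), 4, fold_ids)
  got <- matrix(NA_real_, n_samples(d), length(tiny_space()))
  got[oos$sample_idx, ] <- oos$predictions
  expect_identical(got, unname(ref))
})

test_that("a crashing configuration is excluded and the run continues", {
  fx <- generate_fixture(fixture_spec(n = 40, p = 4, k_informative = 1, seed = 9))
  bad <- single_config()
  bad$classifier$family <- "not_a_family"
  space <- c(tiny_space()[1:2], list(bad))
  plan <- plan_protocol(compute_meta_features(fx$dataset), R = 1, K = 4, seed = 1)
  oos <- run_gcv(fx$dataset, space, plan)
  expect_equal(oos$failed, c(FALSE, FALSE, TRUE))
  expect_false(anyNA(oos$predictions[, 1:2]))
})

test_that("early_drop keeps an identical challenger and drops a flipped one", {
  set.seed(13)
  n <- 200
  y <- factor(rep(c("neg", "pos"), n / 2))
  strong <- ifelse(y == "pos", 0.8, 0.2) + rnorm(n, sd = 0.1)
  expect_false(early_drop(strong, strong, y, positive = "pos", seed = 2))
  expect_true(early_drop(1 - strong, strong, y, positive = "pos", seed = 2))
})

test_that("early_drop rarely rejects an equal-quality challenger", {
  set.seed(14)
  drops <- vapply(1:200, function(i) {
    y <- factor(rep(c("neg", "pos"), 40))
    a <- runif(80); b <- runif(80)   # both pure noise, equal quality
    early_drop(a, b, y, positive = "pos", alpha_drop = 0.01, B = 150L, seed = i)
  }, logical(1))
  expect_lte(mean(drops), 5 * 0.01)
})

test_that("early_stop fires on stalled CI widths only", {
  expect_true(early_stop(c(0.20, 0.20)))
  expect_false(early_stop(c(0.20, 0.10)))
  expect_false(early_stop(c(0.20, 0.19)))           # exactly 5% is progress
  expect_true(early_stop(c(0.20, 0.19, 0.189)))     # 0.5% < 5%
})

test_that("dropping leaves the winner unchanged on clear-signal data", {
  fx <- generate_fixture(fixture_spec(n = 60, p = 5, k_informative = 2,
                                      effect_sizes = c(2, 1.5), seed = 21))
  plan <- plan_protocol(compute_meta_features(fx$dataset), R = 2, K = 5, seed = 4)
  full <- run_gcv(fx$dataset, tiny_space(), plan)
  dropped <- run_gcv(fx$dataset, tiny_space(), plan, dropping = TRUE)
  expect_equal(which.max(dropped$pooled_auc * ifelse(dropped$dropped, NA, 1)),
               which.max(full$pooled_auc))
})

test_that("the out-of-sample matrix persists to a readable long table", {
  fx <- generate_fixture(fixture_spec(n = 30, p = 3, k_informative = 1, seed = 10))
  plan <- plan_protocol(compute_meta_features(fx$dataset), R = 1, K = 3, seed = 1)
  oos <- run_gcv(fx$dataset, tiny_space()[1:2], plan)
  path <- withr::local_tempfile(fileext = ".csv.gz")
  write_oos(oos, path)
  back <- read.csv(gzfile(path))
  expect_equal(nrow(back), 60L)
  expect_setequal(unique(back$config), oos$config_ids)
})
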