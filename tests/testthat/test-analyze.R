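# End-to-end orchestration: one run answers every criterion, results are
# reproducible, serializable, and applicable to new data.

small_overrides <- function() list(
  R = 1L, K = 8L,
  selectors = list(
    list(kind = "none", params = list(), aggressive = FALSE),
    list(kind = "ses", params = list(alpha = 0.05, maxk = 2L, max_features = 25L),
         aggressive = FALSE),
    list(kind = "ses", params = list(alpha = 0.005, maxk = 3L, max_features = 25L),
         aggressive = TRUE),
    list(kind = "lasso", params = list(penalty = 0.05, max_features = 25L),
         aggressive = FALSE)),
  classifiers = list(
    list(family = "ridge_logistic", hyper = list(lambda = 0.1)),
    list(family = "ridge_logistic", hyper = list(lambda = 1)),
    list(family = "decision_tree", hyper = list(min_leaf = 3L)),
    list(family = "svm_linear", hyper = list(cost = 1))))

strong_fixture <- function(seed = 11, n = 80, p = 15)
  generate_fixture(fixture_spec(n = n, p = p, k_informative = 2,
                                effect_sizes = c(2, 1.5), minority_fraction = 0.4,
                                seed = seed))

test_that("a strong-signal analysis finds signal and answers all criteria", {
  fx <- strong_fixture(n = 100, p = 20)
  res <- run_analysis(fx$dataset, seed = 5, bootstraps = 300,
                      overrides = small_overrides(), max_interpret = 1L)
  expect_s3_class(res, "autosig_result")
  expect_gt(res$estimate$point, 0.8)
  expect_gt(res$signature$n_signatures, 0)
  # all four criteria answered from the one run, no refit
  expect_named(res$winners, c("performance", "interpretability",
                              "feature_selection", "aggressive_feature_selection"))
  expect_true(all(!is.na(unlist(res$winners))))
  interp_fam <- res$config_table$family[match(res$winners$interpretability,
                                              res$config_table$id)]
  expect_true(interp_fam %in% c("ridge_logistic", "decision_tree",
                                "baseline_majority"))
  fs_id <- res$winners$feature_selection
  expect_true(res$config_table$selector_kind[match(fs_id, res$config_table$id)] != "none")
  # interpretation outputs present for the interpreted features
  expect_lte(length(res$importance), 1L)
  expect_s3_class(res$ice[[1]], "autosig_ice")
})

test_that("the same seed reproduces the analysis exactly", {
  fx <- strong_fixture(21)
  r1 <- run_analysis(fx$dataset, seed = 9, bootstraps = 100,
                     overrides = small_overrides(), interpret = FALSE)
  r2 <- run_analysis(fx$dataset, seed = 9, bootstraps = 100,
                     overrides = small_overrides(), interpret = FALSE)
  expect_identical(r1$estimate$point, r2$estimate$point)
  expect_identical(r1$winners, r2$winners)
  expect_identical(r1$oos$predictions, r2$oos$predictions)
})

test_that("results serialize to JSON and a readable report", {
  fx <- strong_fixture(31)
  res <- run_analysis(fx$dataset, seed = 2, bootstraps = 100,
                      overrides = small_overrides(), interpret = FALSE)
  jp <- withr::local_tempfile(fileext = ".json")
  write_results_json(res, jp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$estimate$corrected, res$estimate$point, tolerance = 1e-12)
  expect_equal(back$n_configurations, res$n_configurations)
  expect_equal(back$seed, res$seed)
  rp <- withr::local_tempfile(fileext = ".txt")
  write_report(res, rp)
  txt <- readLines(rp)
  expect_true(any(grepl("winning pipeline", txt)))
  expect_true(any(grepl("constant_removal -> mean_mode_impute", txt)))
})

test_that("a saved model predicts new tables, labeled tables and single records", {
  fx <- strong_fixture(41)
  halves <- stratified_split(fx$dataset, 0.5, seed = 3)
  res <- run_analysis(halves$a, seed = 4, bootstraps = 100,
                      overrides = small_overrides(), interpret = FALSE)
  pred <- apply_model(res$model, halves$b)
  expect_length(pred$probabilities, n_samples(halves$b))
  expect_true(all(pred$probabilities >= 0 & pred$probabilities <= 1))
  expect_gt(pred$auc, 0.6)                 # labeled: external validation AUC
  expect_true(all(c("fpr", "tpr") %in% names(pred$roc)))
  # single manual record, via the serialized model file
  mp <- withr::local_tempfile(fileext = ".rds")
  save_model(res$model, mp)
  rec <- as.list(halves$b$values[1, , drop = FALSE])
  one <- apply_model(mp, rec)
  expect_length(one$probabilities, 1L)
  # a record missing a signature feature is rejected
  rec$f001 <- NULL
  expect_error(apply_model(mp, rec), class = "autosig_schema_mismatch")
})

test_that("an analysis from CSV matches one from the in-memory dataset", {
  fx <- strong_fixture(51)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(fx$dataset, path, outcome_column = "y")
  res_csv <- run_analysis(path, outcome = "y", seed = 6, bootstraps = 50,
                          overrides = small_overrides(), interpret = FALSE)
  res_mem <- run_analysis(fx$dataset, seed = 6, bootstraps = 50,
                          overrides = small_overrides(), interpret = FALSE)
  expect_equal(res_csv$estimate$point, res_mem$estimate$point, tolerance = 1e-9)
})
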