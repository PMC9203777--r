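# Shared fixture builders and the compact simulation-study grid.

# a small deterministic-classifier space (no forest) for exact-equality tests
tiny_space <- function() {
  sels <- list(list(kind = "none", params = list(), aggressive = FALSE),
               list(kind = "lasso", params = list(penalty = 0.05, max_features = 25L),
                    aggressive = FALSE))
  cls <- list(list(family = "ridge_logistic", hyper = list(lambda = 0.1)),
              list(family = "decision_tree", hyper = list(min_leaf = 3L)),
              list(family = "svm_linear", hyper = list(cost = 1)))
  space <- list()
  for (s in sels) for (cl in cls)
    space <- c(space, list(autosig:::new_configuration(s, cl)))
  space
}

single_config <- function(family = "ridge_logistic", hyper = list(lambda = 0.1),
                          selector = list(kind = "none", params = list(),
                                          aggressive = FALSE)) {
  autosig:::new_configuration(selector, list(family = family, hyper = hyper))
}

# the simulation-study configuration grid: 101 diverse, fast pipelines
# (none + three lasso-penalty selectors crossed with ridge, tree, linear and
# RBF SVM and small-forest classifiers, plus the baseline)
study_overrides <- function() {
  sels <- list(list(kind = "none", params = list(), aggressive = FALSE))
  for (pen in c(0.02, 0.05, 0.1))
    sels <- c(sels, list(list(kind = "lasso",
                              params = list(penalty = pen, max_features = 25L),
                              aggressive = FALSE)))
  cls <- list()
  for (l in c(0.01, 0.1, 1, 10))
    cls <- c(cls, list(list(family = "ridge_logistic", hyper = list(lambda = l))))
  for (ml in c(1L, 3L, 5L))
    cls <- c(cls, list(list(family = "decision_tree", hyper = list(min_leaf = ml))))
  for (co in c(0.1, 1, 10, 100))
    cls <- c(cls, list(list(family = "svm_linear", hyper = list(cost = co))))
  for (co in c(0.1, 1, 10, 100)) for (ga in c(0.01, 0.1, 1))
    cls <- c(cls, list(list(family = "svm_rbf", hyper = list(cost = co, gamma = ga))))
  for (mt in c(5L, 14L))
    cls <- c(cls, list(list(family = "random_forest",
                            hyper = list(num_trees = 100L, mtry = mt))))
  list(selectors = sels, classifiers = cls, R = 1L)
}

# one simulated study: generate 2n samples, analyze one stratified half,
# score the final model on the held-back half
run_study <- function(seed, n = 100L, p = 200L, k_informative = 0L,
                      effect_sizes = c(1.2, 1.0, 0.8), B = 500L) {
  fx <- generate_fixture(fixture_spec(
    n = 2L * n, p = p, k_informative = k_informative,
    effect_sizes = effect_sizes, minority_fraction = 0.4, seed = seed))
  halves <- stratified_split(fx$dataset, 0.5, seed = seed)
  res <- run_analysis(halves$a, seed = seed, bootstraps = B,
                      dropping = FALSE, stopping = FALSE,
                      overrides = study_overrides(), interpret = FALSE,
                      thresholds = FALSE)
  holdout <- auc(predict(res$model, halves$b), halves$b$outcome,
                 positive = halves$b$positive)
  list(unadjusted = res$estimate$unadjusted,
       corrected = res$estimate$point,
       ci_low = res$estimate$ci_low, ci_high = res$estimate$ci_high,
       holdout = holdout)
}

# memoised heavy studies shared by the winner's-curse and coverage checks
study_cache <- new.env(parent = emptyenv())
get_studies <- function(kind = c("null", "signal"), n_runs = 30L) {
  kind <- match.arg(kind)
  key <- paste0(kind, "_", n_runs)
  if (is.null(study_cache[[key]])) {
    k <- if (kind == "null") 0L else 3L
    study_cache[[key]] <- lapply(seq_len(n_runs), function(i)
      run_study(seed = 1000L * (i + (kind == "signal") * 100L) + 7L,
                k_informative = k))
  }
  study_cache[[key]]
}
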