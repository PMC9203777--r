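# Configuration space: rule-based generation of the pipeline grid from the
# dataset's meta-features, and post-analysis selection of the winning
# configuration for each user criterion. All four criteria are answerable
# from a single run: criterion selection only filters and re-ranks the
# per-configuration results, nothing is refit.

CRITERIA <- c("performance", "interpretability", "feature_selection",
              "aggressive_feature_selection")

INTERPRETABLE_FAMILIES <- c("baseline_majority", "decision_tree", "ridge_logistic")

# tie-break order: simpler families first
FAMILY_ORDER <- c(baseline_majority = 1, ridge_logistic = 2, decision_tree = 3,
                  svm_linear = 4, svm_poly = 4, svm_rbf = 4, random_forest = 5)

#' Default hyper-parameter grids
#'
#' The classifier and selector grids crossed by [generate_space()]. Every
#' entry can be overridden.
#' @return named list of grids.
#' @export
default_grids <- function() {
  list(
    ridge_lambda = c(0.01, 0.1, 1, 10),
    svm_cost = c(0.1, 1, 10, 100),
    svm_gamma = c(0.01, 0.1, 1),
    svm_degree = c(2L, 3L),
    tree_min_leaf = c(1L, 3L, 5L),
    forest_trees = c(100L, 1000L),
    ses_alpha_small_n = c(0.01, 0.05, 0.1),
    ses_alpha_large_n = c(0.05),
    ses_maxk = c(2L, 3L),
    lasso_penalty = c(0.01, 0.05, 0.1),
    max_features = 25L,
    max_configurations = 5000L
  )
}

new_configuration <- function(selector, classifier) {
  conf <- list(
    preprocessing = TRANSFORM_KINDS,
    selector = selector,      # list(kind=, params=, aggressive=)
    classifier = classifier,  # list(family=, hyper=)
    id = NA_character_
  )
  conf$id <- configuration_id(conf)
  structure(conf, class = "autosig_configuration")
}

# stable, readable, content-derived identifier
configuration_id <- function(conf) {
  sel <- conf$selector
  sel_str <- switch(sel$kind,
    none = "none",
    ses = sprintf("ses(a=%g,k=%d%s)", sel$params$alpha, sel$params$maxk,
                  if (isTRUE(sel$aggressive)) ",agg" else ""),
    lasso = sprintf("lasso(pen=%g)", sel$params$penalty))
  hp <- conf$classifier$hyper
  hp_str <- if (length(hp) == 0L) "" else
    paste0("(", paste(sprintf("%s=%s", names(hp),
                              vapply(hp, function(v) format(v, digits = 8), character(1))),
                      collapse = ","), ")")
  paste0(sel_str, "+", conf$classifier$family, hp_str)
}

#' @export
print.autosig_configuration <- function(x, ...) {
  cat("<autosig_configuration>", x$id, "\n")
  invisible(x)
}

#' Generate the configuration space
#'
#' Crosses the canonical preprocessing chain with a selector grid and a
#' classifier grid, filtered by meta-feature rules: small samples
#' (n < 100) widen the selection significance grid; larger samples add the
#' LASSO penalty grid; very high dimensionality (p > 10,000) drops the
#' polynomial SVM; a rare minority class caps the forest leaf size. The
#' baseline classifier is always present, so the space is never empty. A
#' hard cap bounds the space with deterministic stride thinning.
#'
#' @param m an `autosig_meta` from [compute_meta_features()].
#' @param overrides named list; any element of [default_grids()] can be
#'   replaced, and `selectors` / `classifiers` can supply explicit lists of
#'   selector / classifier specs that replace the generated grids.
#' @return list of `autosig_configuration`, deterministic in its inputs.
#' @export
generate_space <- function(m, overrides = list()) {
  g <- utils::modifyList(default_grids(), overrides[names(overrides) %in%
                                                    names(default_grids())])
  selectors <- overrides$selectors %||% {
    alphas <- if (m$n < 100) g$ses_alpha_small_n else g$ses_alpha_large_n
    sels <- list(list(kind = "none", params = list(), aggressive = FALSE))
    for (a in alphas) for (k in g$ses_maxk)
      sels <- c(sels, list(list(kind = "ses",
                                params = list(alpha = a, maxk = k,
                                              max_features = g$max_features),
                                aggressive = FALSE)))
    # aggressive variant: alpha/10 and maxk+1 relative to the grid
    for (a in alphas) for (k in g$ses_maxk)
      sels <- c(sels, list(list(kind = "ses",
                                params = list(alpha = a / 10, maxk = k + 1L,
                                              max_features = g$max_features),
                                aggressive = TRUE)))
    if (m$n >= 100)
      for (pen in g$lasso_penalty)
        sels <- c(sels, list(list(kind = "lasso",
                                  params = list(penalty = pen,
                                                max_features = g$max_features),
                                  aggressive = FALSE)))
    sels
  }
  classifiers <- overrides$classifiers %||% {
    cls <- list()
    for (ml in g$tree_min_leaf)
      cls <- c(cls, list(list(family = "decision_tree",
                              hyper = list(min_leaf = ml, criterion = "gini"))))
    for (l in g$ridge_lambda)
      cls <- c(cls, list(list(family = "ridge_logistic", hyper = list(lambda = l))))
    forest_leaf <- if (m$rarest_class < 15) max(1L, m$rarest_class %/% 5L) else 1L
    for (nt in g$forest_trees)
      cls <- c(cls, list(list(family = "random_forest",
                              hyper = list(num_trees = nt, min_leaf = forest_leaf))))
    for (co in g$svm_cost) {
      cls <- c(cls, list(list(family = "svm_linear", hyper = list(cost = co))))
      if (m$p <= 10000)
        for (dg in g$svm_degree)
          cls <- c(cls, list(list(family = "svm_poly",
                                  hyper = list(cost = co, degree = dg, gamma = 0.1))))
      for (ga in g$svm_gamma)
        cls <- c(cls, list(list(family = "svm_rbf",
                                hyper = list(cost = co, gamma = ga))))
    }
    cls
  }
  space <- list(new_configuration(list(kind = "none", params = list(),
                                       aggressive = FALSE),
                                  list(family = "baseline_majority", hyper = list())))
  for (sel in selectors) for (cl in classifiers) {
    if (cl$family == "baseline_majority") next  # one baseline is enough
    space <- c(space, list(new_configuration(sel, cl)))
  }
  if (length(space) == 0L) abort_autosig("empty_space", "no configurations generated")
  if (length(space) > g$max_configurations) {
    keep <- unique(c(1L, round(seq(1L, length(space),
                                   length.out = g$max_configurations))))
    space <- space[keep]
  }
  space
}

#' Select the winning configuration for a criterion
#'
#' Filters configurations by the criterion's admissibility rule, then takes
#' the best estimated performance. `performance` admits everything;
#' `interpretability` admits only humanly interpretable families (ridge
#' logistic, decision tree, baseline); `feature_selection` requires a
#' selector; `aggressive_feature_selection` requires the aggressive
#' selector variant. Ties break toward fewer selected features, then the
#' simpler family, then the lexicographically smaller id.
#'
#' @param results data.frame with one row per configuration: columns `id`,
#'   `auc` (estimated performance), `family`, `selector_kind`, `aggressive`
#'   (logical), `n_features`.
#' @param criterion one of `r paste(CRITERIA, collapse=", ")`.
#' @return the `id` of the winning row.
#' @export
select_winner <- function(results, criterion = "performance") {
  criterion <- match.arg(criterion, CRITERIA)
  adm <- switch(criterion,
    performance = rep(TRUE, nrow(results)),
    interpretability = results$family %in% INTERPRETABLE_FAMILIES,
    feature_selection = results$selector_kind != "none",
    aggressive_feature_selection = results$selector_kind != "none" & results$aggressive)
  if (!any(adm))
    abort_autosig("no_admissible_configuration",
                  sprintf("no configuration satisfies criterion '%s'", criterion))
  r <- results[adm, , drop = FALSE]
  ord <- order(-r$auc, r$n_features, FAMILY_ORDER[r$family], r$id)
  r$id[ord[1]]
}
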