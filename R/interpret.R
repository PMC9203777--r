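# Post-analysis interpretation. Variable importance virtually removes a
# feature by permuting its values (dimensionality and tuned
# hyper-parameters stay untouched) and re-runs the winning configuration's
# cross-validation; the ratio of permuted to original performance measures
# the feature's added value. ICE curves sweep one feature over its
# observed values and trace each sample's predicted probability.

#' Permutation-based individual variable importance
#'
#' Re-runs the winning configuration's GCV with the chosen feature's column
#' permuted (one fresh permutation per repeat) and reports the ratio of the
#' permuted pooled performance to the original pooled performance. Ratios
#' near 1 mean no added predictive value; ratios well below 1 mean the
#' model leans on the feature.
#'
#' @param d an `autosig_dataset`.
#' @param winner an `autosig_configuration`.
#' @param plan an `autosig_gcv_plan` (the original run's plan).
#' @param feature feature name to permute.
#' @param original_auc the winning configuration's pooled AUC from the
#'   original run; computed fresh if NULL.
#' @param seed integer seed for the permutations.
#' @param permutations optional list of explicit permutation index vectors,
#'   one per repeat (overrides the seeded draws; useful for auditing —
#'   the identity permutation reproduces the original run exactly).
#' @return list of class `autosig_importance`: `feature`, `perf_ratio`,
#'   `relative_drop`, `original_auc`, `permuted_auc`.
#' @export
permutation_importance <- function(d, winner, plan, feature,
                                   original_auc = NULL, seed = 1L,
                                   permutations = NULL) {
  if (!feature %in% d$feature_names)
    abort_autosig("feature_not_found", paste("no such feature:", feature))
  if (is.null(original_auc)) {
    oos <- run_gcv(d, list(winner), plan)
    original_auc <- oos$pooled_auc[1]
  }
  preds <- list(); labs <- list()
  for (r in seq_len(plan$R)) {
    perm <- if (!is.null(permutations)) permutations[[r]] else
      with_seed(derive_seed(seed, r), sample(n_samples(d)))
    dp <- d
    dp$values[[feature]] <- d$values[[feature]][perm]
    sub_plan <- plan
    sub_plan$R <- 1L
    oos_r <- run_gcv(dp, list(winner), sub_plan, repeat_offset = r - 1L)
    preds[[r]] <- oos_r$predictions[, 1]
    labs[[r]] <- as.character(oos_r$labels)
  }
  permuted_auc <- auc(unlist(preds),
                      factor(unlist(labs), levels = levels(d$outcome)),
                      positive = d$positive)
  ratio <- permuted_auc / original_auc
  structure(list(feature = feature, perf_ratio = ratio,
                 relative_drop = 1 - ratio,
                 original_auc = original_auc, permuted_auc = permuted_auc),
            class = "autosig_importance")
}

#' @export
print.autosig_importance <- function(x, ...) {
  cat(sprintf("<autosig_importance> %s: ratio %.3f (original %.3f, permuted %.3f)\n",
              x$feature, x$perf_ratio, x$original_auc, x$permuted_auc))
  invisible(x)
}

#' Individual conditional expectation curve
#'
#' For each sample, predicts while one feature sweeps the sorted observed
#' values it takes in the data; the mean over samples is the mean-effect
#' curve and the 2.5/97.5 percentiles across per-sample lines form the
#' band. Narrow bands mean the prediction is dominated by this feature;
#' wide bands mean the model leans on others too.
#'
#' @param model an `autosig_model`.
#' @param d an `autosig_dataset` providing the samples and the observed
#'   value grid.
#' @param feature feature name.
#' @param max_grid cap on grid points (observed values are evenly
#'   subsampled beyond it).
#' @param keep_lines keep the per-sample line matrix.
#' @return list of class `autosig_ice`: `feature`, `grid`, `mean_curve`,
#'   `band_low`, `band_high`, optional `lines` (samples x grid).
#' @export
ice_curve <- function(model, d, feature, max_grid = 200L, keep_lines = FALSE) {
  if (!feature %in% colnames(d$values))
    abort_autosig("feature_not_found", paste("no such feature:", feature))
  obs <- d$values[[feature]]
  grid <- sort(unique(obs[!is.na(obs)]))
  if (length(grid) > max_grid)
    grid <- grid[unique(round(seq(1, length(grid), length.out = max_grid)))]
  lines <- vapply(grid, function(chi) {
    tbl <- d$values
    tbl[[feature]] <- rep(chi, nrow(tbl))
    predict(model, tbl)
  }, numeric(n_samples(d)))
  lines <- matrix(lines, nrow = n_samples(d))
  structure(list(feature = feature, grid = grid,
                 mean_curve = colMeans(lines),
                 band_low = apply(lines, 2, stats::quantile, 0.025, names = FALSE),
                 band_high = apply(lines, 2, stats::quantile, 0.975, names = FALSE),
                 lines = if (keep_lines) lines else NULL),
            class = "autosig_ice")
}

#' @export
print.autosig_ice <- function(x, ...) {
  cat(sprintf("<autosig_ice> %s over %d grid points; mean range [%.3f, %.3f]\n",
              x$feature, length(x$grid), min(x$mean_curve), max(x$mean_curve)))
  invisible(x)
}
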