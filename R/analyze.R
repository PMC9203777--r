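# End-to-end analysis: meta-features -> configuration space -> GCV ->
# BBC correction -> final model, signatures and interpretation. One run
# answers all four user criteria (performance, interpretability, feature
# selection, aggressive feature selection) post hoc: criterion choice only
# filters the stored per-configuration results, nothing is refit.

#' Run a full automated analysis
#'
#' @param data an `autosig_dataset`, or a CSV path (then `outcome` and
#'   optionally `group` name the columns).
#' @param outcome,group column names when `data` is a path.
#' @param criterion the criterion whose winner is finalized into a model:
#'   `r paste(CRITERIA, collapse=", ")`. Winners for all four criteria are
#'   reported regardless.
#' @param seed master seed; expanded deterministically into per-stage seeds.
#' @param bootstraps BBC bootstrap count B.
#' @param dropping,stopping enable the GCV search heuristics.
#' @param overrides named list forwarded to [generate_space()]; may also
#'   carry `R`, `K`, `N` to override the protocol plan.
#' @param interpret compute permutation importance and ICE curves for the
#'   final signature (capped at `max_interpret` features).
#' @param max_interpret cap on interpreted features.
#' @param thresholds compute the BBC-corrected threshold metrics / adjusted
#'   ROC for the winner (skippable for simulation studies that only need
#'   the corrected AUC).
#' @param threshold_count thresholds for the adjusted ROC (default 10).
#' @param verbose log progress via `message()`.
#' @return object of class `autosig_result`: `meta`, `plan`,
#'   `n_configurations`, `config_table`, `winners` (per criterion),
#'   `criterion`, `estimate` (BBC-corrected, for the chosen criterion's
#'   admissible set), `thresholds`, `model`, `signature`, `importance`,
#'   `ice`, `seed`, `version`.
#' @export
run_analysis <- function(data, outcome = NULL, group = NULL,
                         criterion = "performance", seed = 1L,
                         bootstraps = 1000L, dropping = TRUE, stopping = TRUE,
                         overrides = list(), interpret = TRUE,
                         max_interpret = 10L, thresholds = TRUE,
                         threshold_count = 10L, verbose = FALSE) {
  criterion <- match.arg(criterion, CRITERIA)
  say <- function(...) if (verbose) message(sprintf(...))
  d <- if (inherits(data, "autosig_dataset")) data else {
    if (is.null(outcome)) abort_autosig("bad_input", "outcome column name required")
    read_dataset(data, outcome, group_column = group)
  }
  meta <- compute_meta_features(d)
  say("data: n=%d p=%d rarest=%d missing=%.1f%%",
      meta$n, meta$p, meta$rarest_class, 100 * meta$missing_fraction)
  space <- generate_space(meta, overrides)
  say("configurations generated: %d", length(space))
  plan <- plan_protocol(meta, R = overrides$R, K = overrides$K, N = overrides$N,
                        seed = derive_seed(seed, 11L))
  say("protocol: R=%d K=%d N=%d", plan$R, plan$K, plan$N)
  oos <- run_gcv(d, space, plan, dropping = dropping, stopping = stopping)
  say("GCV done: %d predictions, %d dropped, %d failed, %d repeat(s) completed",
      nrow(oos$predictions), sum(oos$dropped), sum(oos$failed),
      oos$completed_repeats)

  config_table <- data.frame(
    id = oos$config_ids,
    auc = oos$pooled_auc,
    family = vapply(space, function(cf) cf$classifier$family, character(1)),
    selector_kind = vapply(space, function(cf) cf$selector$kind, character(1)),
    aggressive = vapply(space, function(cf) isTRUE(cf$selector$aggressive), logical(1)),
    n_features = oos$n_features,
    dropped = oos$dropped, failed = oos$failed,
    stringsAsFactors = FALSE)

  alive_tab <- config_table[!config_table$dropped & !config_table$failed &
                              !is.na(config_table$auc), , drop = FALSE]
  winners <- lapply(stats::setNames(CRITERIA, CRITERIA), function(cr)
    tryCatch(select_winner(alive_tab, cr), autosig_error = function(e) NA_character_))

  win_id <- winners[[criterion]]
  if (is.na(win_id))
    abort_autosig("no_admissible_configuration",
                  sprintf("criterion '%s' admits no surviving configuration", criterion))
  estimate <- bbc_correct(subset_oos(oos, admissible_ids(alive_tab, criterion)),
                          B = bootstraps, seed = derive_seed(seed, 22L))
  say("BBC (B=%d): corrected %.3f [%.3f, %.3f], unadjusted %.3f",
      estimate$B, estimate$point, estimate$ci_low, estimate$ci_high,
      estimate$unadjusted)

  winner_conf <- space[[match(win_id, oos$config_ids)]]
  model <- finalize(d, winner_conf, seed = derive_seed(seed, 33L))
  wcol <- oos$predictions[, match(win_id, oos$config_ids)]
  okr <- !is.na(wcol)
  threshold_metrics <- if (thresholds)
    bbc4rocs(wcol[okr], oos$labels[okr], positive = d$positive,
             T = threshold_count, B = min(bootstraps, 500L),
             seed = derive_seed(seed, 44L),
             sample_ids = oos$sample_idx[okr]) else NULL

  importance <- NULL; ice <- NULL
  if (interpret && length(model$features) > 0L) {
    feats <- decode_features(model$features, d)
    feats <- utils::head(feats, max_interpret)
    original_auc <- oos$pooled_auc[match(win_id, oos$config_ids)]
    importance <- lapply(feats, function(f)
      permutation_importance(d, winner_conf, plan, f,
                             original_auc = original_auc,
                             seed = derive_seed(seed, 55L)))
    names(importance) <- feats
    ice <- lapply(feats, function(f) ice_curve(model, d, f))
    names(ice) <- feats
  }

  structure(list(meta = meta, plan = plan,
                 n_configurations = length(space),
                 config_table = config_table,
                 winners = winners, criterion = criterion,
                 estimate = estimate, thresholds = threshold_metrics,
                 model = model, signature = model$signature,
                 importance = importance, ice = ice,
                 oos = oos, seed = as.integer(seed),
                 version = "autosig-result-1"),
            class = "autosig_result")
}

admissible_ids <- function(tab, criterion) {
  adm <- switch(criterion,
    performance = rep(TRUE, nrow(tab)),
    interpretability = tab$family %in% INTERPRETABLE_FAMILIES,
    feature_selection = tab$selector_kind != "none",
    aggressive_feature_selection = tab$selector_kind != "none" & tab$aggressive)
  tab$id[adm]
}

subset_oos <- function(oos, ids) {
  keep <- match(ids, oos$config_ids)
  out <- oos
  out$predictions <- oos$predictions[, keep, drop = FALSE]
  out$config_ids <- oos$config_ids[keep]
  out$dropped <- oos$dropped[keep]
  out$failed <- oos$failed[keep]
  out$pooled_auc <- oos$pooled_auc[keep]
  out$n_features <- oos$n_features[keep]
  out
}

# map encoded one-hot names back to source features for interpretation
decode_features <- function(feats, d) {
  raw <- sub("=.*$", "", feats)
  unique(raw[raw %in% d$feature_names | raw %in% colnames(d$values)])
}

#' @export
print.autosig_result <- function(x, ...) {
  cat(sprintf("<autosig_result> %d configurations, criterion '%s'\n",
              x$n_configurations, x$criterion))
  cat(sprintf("  winner: %s\n", x$winners[[x$criterion]]))
  cat(sprintf("  corrected AUC %.3f [%.3f, %.3f] (unadjusted %.3f)\n",
              x$estimate$point, x$estimate$ci_low, x$estimate$ci_high,
              x$estimate$unadjusted))
  if (x$signature$n_signatures > 0)
    cat(sprintf("  signature(s): %d of size %d\n", x$signature$n_signatures,
                length(x$signature$equivalence_classes)))
  invisible(x)
}

#' Write the analysis result as JSON
#'
#' Structured, versioned results: dataset summary, per-configuration table,
#' winners per criterion, corrected estimates with CIs, threshold table,
#' signatures, importance records and seeds.
#' @param res an `autosig_result`
#' @param path output path
#' @export
write_results_json <- function(res, path) {
  out <- list(
    version = res$version,
    seed = res$seed,
    dataset = list(n = res$meta$n, p = res$meta$p,
                   class_counts = as.list(res$meta$class_counts),
                   missing_fraction = res$meta$missing_fraction),
    protocol = list(R = res$plan$R, K = res$plan$K, N = res$plan$N,
                    completed_repeats = res$oos$completed_repeats),
    n_configurations = res$n_configurations,
    n_dropped = sum(res$config_table$dropped),
    n_failed = sum(res$config_table$failed),
    criterion = res$criterion,
    winners = res$winners,
    estimate = list(metric = res$estimate$metric_name,
                    corrected = res$estimate$point,
                    ci_low = res$estimate$ci_low,
                    ci_high = res$estimate$ci_high,
                    unadjusted = res$estimate$unadjusted,
                    bootstraps = res$estimate$B),
    thresholds = res$thresholds$table,
    roc = res$thresholds$roc,
    signature = list(
      equivalence_classes = res$signature$equivalence_classes,
      n_signatures = res$signature$n_signatures,
      signatures = res$signature$signatures),
    importance = if (is.null(res$importance)) NULL else
      data.frame(feature = names(res$importance),
                 perf_ratio = vapply(res$importance, `[[`, numeric(1), "perf_ratio"),
                 relative_drop = vapply(res$importance, `[[`, numeric(1), "relative_drop"),
                 row.names = NULL),
    config_table = res$config_table
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a human-readable analysis report
#'
#' Plain-text report mirroring the pipeline: dataset summary, protocol,
#' winning configuration per criterion (stage names plus hyper-parameter
#' values), corrected performance with CI, signatures, threshold table and
#' importance ranking.
#' @param res an `autosig_result`
#' @param path output path
#' @export
write_report <- function(res, path) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("automated biosignature analysis report (schema %s)", res$version)
  add("====================================================")
  add("data: %d samples x %d features; classes %s; missing %.1f%%",
      res$meta$n, res$meta$p,
      paste(sprintf("%s=%d", names(res$meta$class_counts), res$meta$class_counts),
            collapse = "/"),
      100 * res$meta$missing_fraction)
  add("protocol: stratified %d-repeated %d-fold CV, %d fold(s) per repeat; %d repeat(s) completed",
      res$plan$R, res$plan$K, res$plan$N, res$oos$completed_repeats)
  add("configurations: %d generated, %d dropped early, %d failed; bootstraps B=%d",
      res$n_configurations, sum(res$config_table$dropped),
      sum(res$config_table$failed), res$estimate$B)
  add("")
  add("winning configuration per criterion:")
  for (cr in names(res$winners))
    add("  %-30s %s", cr, res$winners[[cr]] %||% "(none admissible)")
  add("")
  add("selected criterion: %s", res$criterion)
  add("winning pipeline: %s -> %s", paste(res$model$configuration$preprocessing,
                                          collapse = " -> "),
      res$model$configuration$id)
  add("corrected AUC: %.3f (95%% CI %.3f-%.3f); unadjusted: %.3f",
      res$estimate$point, res$estimate$ci_low, res$estimate$ci_high,
      res$estimate$unadjusted)
  if (res$signature$n_signatures > 0) {
    add("")
    add("signatures: %d equivalent signature(s) of size %d",
        res$signature$n_signatures, length(res$signature$equivalence_classes))
    for (i in seq_along(res$signature$equivalence_classes))
      add("  slot %d: {%s}", i,
          paste(res$signature$equivalence_classes[[i]], collapse = ", "))
  }
  if (!is.null(res$importance)) {
    add("")
    add("variable importance (permuted/original AUC ratio; lower = more important):")
    for (f in names(res$importance))
      add("  %-20s %.3f", f, res$importance[[f]]$perf_ratio)
  }
  if (!is.null(res$thresholds)) {
  add("")
  add("threshold metrics (BBC corrected), accuracy-optimal %.3f, balanced-accuracy-optimal %.3f:",
      res$thresholds$best_accuracy_threshold,
      res$thresholds$best_balanced_accuracy_threshold)
  tab <- res$thresholds$table
  for (t in unique(tab$threshold)) {
    row <- tab[tab$threshold == t, ]
    add("  t=%.3f  sens %.2f  spec %.2f  acc %.2f  bacc %.2f",
        t, row$point[row$metric == "sensitivity"],
        row$point[row$metric == "specificity"],
        row$point[row$metric == "accuracy"],
        row$point[row$metric == "balanced_accuracy"])
  }
  }
  writeLines(ln, path)
  invisible(path)
}

#' Apply a final model to new data
#'
#' Batch prediction on a table (or a single manually-entered record). When
#' the table carries the outcome column, external-validation metrics
#' (holdout AUC and a plain ROC) are computed as well.
#'
#' @param model an `autosig_model` or a path to one saved by [save_model()].
#' @param newdata data.frame, `autosig_dataset`, CSV path, or a named list
#'   giving one value per feature (manual single-sample input).
#' @param outcome optional outcome column name for labeled validation.
#' @return list of class `autosig_predictions`: `probabilities`, `positive`,
#'   and, when labels are present, `auc` and `roc` (FPR/TPR points).
#' @export
apply_model <- function(model, newdata, outcome = NULL) {
  if (is.character(model)) model <- load_model(model)
  if (is.character(newdata)) newdata <- utils::read.csv(newdata, check.names = FALSE)
  if (!is.data.frame(newdata) && !inherits(newdata, "autosig_dataset")) {
    newdata <- as.data.frame(newdata[!vapply(newdata, is.null, logical(1))],
                             check.names = FALSE)  # single manual record
  }
  labels <- NULL
  if (inherits(newdata, "autosig_dataset")) {
    labels <- newdata$outcome
  } else if (!is.null(outcome) && outcome %in% colnames(newdata)) {
    labels <- factor(newdata[[outcome]])
    newdata <- newdata[, setdiff(colnames(newdata), outcome), drop = FALSE]
  }
  pr <- predict(model, newdata)
  out <- list(probabilities = pr, positive = model$positive)
  if (!is.null(labels) && length(unique(labels)) == 2L) {
    out$auc <- auc(pr, labels, positive = model$positive)
    ts <- sort(unique(pr), decreasing = TRUE)
    pos <- labels == model$positive
    out$roc <- data.frame(
      threshold = ts,
      fpr = vapply(ts, function(t) mean(pr[!pos] >= t), numeric(1)),
      tpr = vapply(ts, function(t) mean(pr[pos] >= t), numeric(1)))
  }
  structure(out, class = "autosig_predictions")
}

#' @export
print.autosig_predictions <- function(x, ...) {
  cat(sprintf("<autosig_predictions> %d prediction(s), positive class '%s'\n",
              length(x$probabilities), x$positive))
  if (!is.null(x$auc)) cat(sprintf("  validation AUC: %.3f\n", x$auc))
  invisible(x)
}
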