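# Performance metrics and bootstrap bias correction. Selecting the
# best-looking configuration among many inflates its cross-validated
# estimate (the winner's curse). BBC removes that optimism by
# bootstrapping the selection step itself on the pooled out-of-sample
# prediction matrix: each replicate re-selects a winner on the in-bag
# rows and scores that pick on the out-of-bag rows.

#' Area under the ROC curve
#'
#' Probability that a random positive outranks a random negative, ties
#' counted one half (the scaled Mann-Whitney U statistic).
#'
#' @param predictions numeric score vector.
#' @param labels outcome factor (or vector) with both classes present.
#' @param positive the positive class level; defaults to the
#'   lexicographically larger one.
#' @return AUC in [0,1].
#' @export
auc <- function(predictions, labels, positive = NULL) {
  labels <- factor(labels)
  positive <- positive %||% max(levels(labels))
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    abort_autosig("single_class", "AUC needs both classes among the labels")
  r <- rank(predictions, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# AUC for every column of a prediction matrix (shared rank bookkeeping)
auc_columns <- function(P, pos_mask) {
  n1 <- sum(pos_mask); n0 <- sum(!pos_mask)
  vapply(seq_len(ncol(P)), function(j) {
    r <- rank(P[, j], ties.method = "average")
    (sum(r[pos_mask]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
}

#' Bootstrap bias corrected performance estimate (BBC-CV)
#'
#' Bootstraps the configuration-selection strategy on the out-of-sample
#' prediction matrix: for each of B replicates, samples are drawn with
#' replacement (all repeats of a sample move together), the best
#' configuration on the in-bag rows is identified, and that pick is scored
#' on the out-of-bag rows. The corrected point estimate is the mean of the
#' B out-of-bag values; the 95% CI its 2.5/97.5 percentiles. Replicates
#' whose out-of-bag part lacks a class are redrawn (capped at 10xB
#' attempts). The reported winner is the argmax on the full, un-resampled
#' matrix, whose plain pooled estimate is returned as `unadjusted`.
#'
#' @param oos an `autosig_oos` from [run_gcv()] (dropped/failed
#'   configurations are excluded from selection).
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return list of class `autosig_corrected`: `metric_name`, `point`,
#'   `ci_low`, `ci_high`, `unadjusted`, `B`, `winner_id`, `samples`
#'   (the B out-of-bag values), `redraws`.
#' @export
bbc_correct <- function(oos, B = 1000L, seed = 1L) {
  keep <- !oos$dropped & !oos$failed & !is.na(oos$pooled_auc)
  if (!any(keep)) abort_autosig("no_survivors", "no surviving configuration")
  P <- oos$predictions[, keep, drop = FALSE]
  ok_rows <- stats::complete.cases(P)
  P <- P[ok_rows, , drop = FALSE]
  labels <- oos$labels[ok_rows]
  sample_of_row <- oos$sample_idx[ok_rows]
  pos_mask <- labels == oos$positive
  usamp <- unique(sample_of_row)
  rows_by_samp <- split(seq_along(sample_of_row), match(sample_of_row, usamp))
  ns <- length(usamp)

  vals <- numeric(B)
  redraws <- 0L
  with_seed(seed, {
    b <- 1L
    while (b <= B) {
      inb_s <- sample.int(ns, ns, replace = TRUE)
      oob_s <- setdiff(seq_len(ns), inb_s)
      inb_rows <- unlist(rows_by_samp[inb_s], use.names = FALSE)
      oob_rows <- unlist(rows_by_samp[oob_s], use.names = FALSE)
      if (length(oob_rows) == 0L ||
          length(unique(pos_mask[oob_rows])) < 2L ||
          length(unique(pos_mask[inb_rows])) < 2L) {
        redraws <- redraws + 1L
        if (redraws > 10L * B)
          abort_autosig("degenerate_bootstrap",
                        "could not draw non-degenerate bootstrap replicates")
        next
      }
      perf_in <- auc_columns(P[inb_rows, , drop = FALSE], pos_mask[inb_rows])
      pick <- which.max(perf_in)
      vals[b] <- auc(P[oob_rows, pick], labels[oob_rows], oos$positive)
      b <- b + 1L
    }
  })
  full_perf <- auc_columns(P, pos_mask)
  win <- which.max(full_perf)
  ci <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  structure(list(metric_name = "auc",
                 point = mean(vals),
                 ci_low = ci[1], ci_high = ci[2],
                 unadjusted = full_perf[win],
                 B = as.integer(B),
                 winner_id = colnames(P)[win],
                 samples = vals,
                 redraws = redraws),
            class = "autosig_corrected")
}

#' @export
print.autosig_corrected <- function(x, ...) {
  cat(sprintf("<autosig_corrected> %s = %.3f [%.3f, %.3f] (unadjusted %.3f, B=%d)\n",
              x$metric_name, x$point, x$ci_low, x$ci_high, x$unadjusted, x$B))
  cat("  winner:", x$winner_id, "\n")
  invisible(x)
}

threshold_metric_names <- c("sensitivity", "specificity", "accuracy",
                            "balanced_accuracy", "precision", "f1")

threshold_metrics_at <- function(pred, pos_mask, t) {
  call_pos <- pred >= t
  tp <- sum(call_pos & pos_mask); fn <- sum(!call_pos & pos_mask)
  fp <- sum(call_pos & !pos_mask); tn <- sum(!call_pos & !pos_mask)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  prec <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  f1 <- if (is.na(prec) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  c(sensitivity = sens, specificity = spec,
    accuracy = (tp + tn) / length(pred),
    balanced_accuracy = (sens + spec) / 2,
    precision = prec, f1 = f1,
    fpr = 1 - spec, tpr = sens)
}

#' Threshold-dependent metrics with bootstrap confidence intervals
#'
#' Computes sensitivity, specificity, accuracy, balanced accuracy,
#' precision and F1 at T classification thresholds placed at the
#' k/(T+1) quantiles of the winner's pooled out-of-sample predictions, so
#' the prediction distribution is divided into T+1 equal-probability
#' regions. Each metric is bootstrap corrected with the same sample-level
#' resampling as [bbc_correct()]: per replicate the metrics are evaluated
#' on the out-of-bag rows, giving a point estimate (mean) and a 95%
#' percentile CI, including the per-threshold (FPR, TPR) CI "cross" that
#' makes up the adjusted ROC curve.
#'
#' @param pred the winner's pooled out-of-sample predictions.
#' @param labels aligned outcome factor.
#' @param positive positive class level.
#' @param T threshold count (default 10).
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @param sample_ids optional sample identifier per row so repeated
#'   measurements of a sample resample together.
#' @return list of class `autosig_thresholds`: `thresholds`, `table`
#'   (data.frame: threshold, metric, point, ci_low, ci_high),
#'   `roc` (threshold, fpr, tpr and their CIs), `best_accuracy_threshold`,
#'   `best_balanced_accuracy_threshold`.
#' @export
bbc4rocs <- function(pred, labels, positive = NULL, T = 10L, B = 500L,
                     seed = 1L, sample_ids = NULL) {
  labels <- factor(labels)
  positive <- positive %||% max(levels(labels))
  pos_mask <- labels == positive
  thr <- stats::quantile(pred, probs = seq_len(T) / (T + 1), names = FALSE)
  if (anyDuplicated(thr)) {
    warning("duplicate thresholds collapsed (few distinct prediction values)")
    thr <- unique(thr)
  }
  sample_ids <- sample_ids %||% seq_along(pred)
  usamp <- unique(sample_ids)
  rows_by_samp <- split(seq_along(pred), match(sample_ids, usamp))
  ns <- length(usamp)
  mnames <- c(threshold_metric_names, "fpr", "tpr")

  boot <- array(NA_real_, c(B, length(thr), length(mnames)),
                dimnames = list(NULL, NULL, mnames))
  with_seed(seed, {
    b <- 1L; attempts <- 0L
    while (b <= B) {
      oob_s <- setdiff(seq_len(ns), sample.int(ns, ns, replace = TRUE))
      oob <- unlist(rows_by_samp[oob_s], use.names = FALSE)
      if (length(oob) == 0L || length(unique(pos_mask[oob])) < 2L) {
        attempts <- attempts + 1L
        if (attempts > 10L * B)
          abort_autosig("degenerate_bootstrap", "bootstrap replicates degenerate")
        next
      }
      for (ti in seq_along(thr))
        boot[b, ti, ] <- threshold_metrics_at(pred[oob], pos_mask[oob], thr[ti])
      b <- b + 1L
    }
  })
  tab <- do.call(rbind, lapply(seq_along(thr), function(ti) {
    do.call(rbind, lapply(mnames, function(mn) {
      v <- boot[, ti, mn]
      data.frame(threshold = thr[ti], metric = mn,
                 point = mean(v, na.rm = TRUE),
                 ci_low = stats::quantile(v, 0.025, na.rm = TRUE, names = FALSE),
                 ci_high = stats::quantile(v, 0.975, na.rm = TRUE, names = FALSE))
    }))
  }))
  roc <- do.call(rbind, lapply(seq_along(thr), function(ti) {
    data.frame(threshold = thr[ti],
               fpr = mean(boot[, ti, "fpr"], na.rm = TRUE),
               fpr_lo = stats::quantile(boot[, ti, "fpr"], 0.025, na.rm = TRUE, names = FALSE),
               fpr_hi = stats::quantile(boot[, ti, "fpr"], 0.975, na.rm = TRUE, names = FALSE),
               tpr = mean(boot[, ti, "tpr"], na.rm = TRUE),
               tpr_lo = stats::quantile(boot[, ti, "tpr"], 0.025, na.rm = TRUE, names = FALSE),
               tpr_hi = stats::quantile(boot[, ti, "tpr"], 0.975, na.rm = TRUE, names = FALSE))
  }))
  acc <- tab[tab$metric == "accuracy", ]
  bac <- tab[tab$metric == "balanced_accuracy", ]
  structure(list(thresholds = thr, table = tab, roc = roc,
                 best_accuracy_threshold = acc$threshold[which.max(acc$point)],
                 best_balanced_accuracy_threshold = bac$threshold[which.max(bac$point)],
                 B = as.integer(B)),
            class = "autosig_thresholds")
}

#' @export
print.autosig_thresholds <- function(x, ...) {
  cat(sprintf("<autosig_thresholds> %d thresholds, B=%d\n", length(x$thresholds), x$B))
  cat(sprintf("  accuracy optimal at %.3f; balanced accuracy optimal at %.3f\n",
              x$best_accuracy_threshold, x$best_balanced_accuracy_threshold))
  invisible(x)
}

#' Fit the final model with the winning configuration
#'
#' Refits the winning pipeline on the full dataset: the final model is
#' trained on all n samples so no sample is lost to estimation. Its
#' reported performance remains the BBC-corrected estimate of the
#' configuration, never a refit estimate.
#'
#' @param d an `autosig_dataset`.
#' @param winner an `autosig_configuration`.
#' @param seed integer seed.
#' @return object of class `autosig_model`: preprocessing chain, signature
#'   set, fitted classifier, training-sample count `n_train`, configuration.
#' @export
finalize <- function(d, winner, seed = 1L) {
  res <- tryCatch({
    pre <- fit_preprocess(d$values)
    sel <- winner$selector
    sig <- switch(sel$kind,
      none = new_signature_set(as.list(colnames(pre$train))),
      ses = ses_select(pre$train, d$outcome, alpha = sel$params$alpha,
                       maxk = sel$params$maxk,
                       max_features = sel$params$max_features %||% 25L),
      lasso = lasso_select(pre$train, d$outcome, penalty = sel$params$penalty,
                           max_features = sel$params$max_features %||% 25L))
    feats <- primary_signature(sig)
    clf <- if (length(feats) == 0L)
      fit_classifier("baseline_majority", list(), matrix(0, n_samples(d), 0L),
                     d$outcome, d$positive, seed)
    else
      fit_classifier(winner$classifier$family, winner$classifier$hyper,
                     pre$train[, feats, drop = FALSE], d$outcome, d$positive, seed)
    list(pre = pre, sig = sig, feats = feats, clf = clf)
  }, error = function(e)
    abort_autosig("refit_failure",
                  sprintf("final refit failed for configuration '%s': %s",
                          winner$id, conditionMessage(e))))
  structure(list(configuration = winner,
                 preprocess = res$pre$chain,
                 signature = res$sig,
                 features = res$feats,
                 classifier = res$clf,
                 n_train = n_samples(d),
                 positive = d$positive,
                 outcome_levels = levels(d$outcome),
                 schema = colnames(d$values),
                 version = "autosig-model-1"),
            class = "autosig_model")
}

#' Predict with a final model
#'
#' @param object an `autosig_model`.
#' @param newdata data.frame (or `autosig_dataset`) with the training
#'   feature schema; extra columns are ignored, missing signature features
#'   are an error.
#' @param ... unused.
#' @return numeric vector of positive-class probabilities.
#' @export
predict.autosig_model <- function(object, newdata, ...) {
  tbl <- if (inherits(newdata, "autosig_dataset")) newdata$values else newdata
  missing_cols <- setdiff(object$schema, colnames(tbl))
  if (length(missing_cols) > 0L)
    abort_autosig("schema_mismatch",
                  paste("input lacks feature column(s):",
                        paste(utils::head(missing_cols, 5), collapse = ", ")))
  tbl <- tbl[, object$schema, drop = FALSE]
  X <- apply_preprocess(object$preprocess, tbl)
  if (length(object$features) == 0L)
    return(predict_proba(object$classifier, matrix(0, nrow(X), 0L)))
  predict_proba(object$classifier, X[, object$features, drop = FALSE])
}

#' @export
print.autosig_model <- function(x, ...) {
  cat("<autosig_model>", x$configuration$id, "\n")
  cat(sprintf("  trained on %d samples; signature: %s\n", x$n_train,
              if (length(x$features)) paste(x$features, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Save / load a final model
#'
#' Serializes the model (preprocessing state included, so prediction needs
#' no original data) with a format version stamp.
#' @param model an `autosig_model`
#' @param path file path
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "autosig_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "autosig_model") || !identical(m$version, "autosig-model-1"))
    abort_autosig("bad_model_file", "not a recognized autosig model file")
  m
}
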