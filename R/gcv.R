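# Generalized cross-validation: a stratified, R-repeated, K-fold,
# N-incomplete protocol. Choosing R/K/N emulates holdout (1,10,1),
# standard K-fold CV (1,K,K), incomplete CV and repeated CV. Every
# configuration is evaluated as an atom: transforms, selector and
# classifier are all fitted inside the training folds only. The pooled
# out-of-sample prediction matrix is the input to BBC correction.

#' Plan the evaluation protocol from meta-features
#'
#' Defaults scale with sample size: tiny samples (n < 100) use
#' K = min(rarest class, 20) folds, complete, repeated 10 times (subject to
#' early stopping); moderate samples (100-999) use 5 x 10-fold CV; large
#' samples (n >= 1000) emulate a 10% holdout (R=1, K=10, N=1). K never
#' exceeds the rarest class count so each fold holds at least one sample of
#' each class.
#'
#' @param m an `autosig_meta`.
#' @param R,K,N optional explicit overrides.
#' @param seed integer seed governing fold assignment.
#' @return list of class `autosig_gcv_plan` with `R`, `K`, `N`,
#'   `stratified` (always TRUE), `seed`.
#' @export
plan_protocol <- function(m, R = NULL, K = NULL, N = NULL, seed = 1L) {
  if (m$rarest_class < 2L)
    abort_autosig("class_too_small", "rarest class has fewer than 2 samples")
  if (is.null(K)) K <- if (m$n < 100) min(m$rarest_class, 20L) else 10L
  K <- min(K, m$rarest_class)
  if (is.null(N)) N <- if (m$n >= 1000) 1L else K
  N <- min(N, K)
  if (is.null(R)) R <- if (m$n < 100) 10L else if (m$n < 1000) 5L else 1L
  stopifnot(K >= 2L, N >= 1L, R >= 1L)
  structure(list(R = as.integer(R), K = as.integer(K), N = as.integer(N),
                 stratified = TRUE, seed = as.integer(seed)),
            class = "autosig_gcv_plan")
}

#' @export
print.autosig_gcv_plan <- function(x, ...) {
  cat(sprintf("<autosig_gcv_plan> R=%d K=%d N=%d stratified seed=%d\n",
              x$R, x$K, x$N, x$seed))
  invisible(x)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of K folds so that every class's per-fold
#' count deviates from proportionality by at most one. With group
#' identifiers, whole groups are placed in a single fold (greedy, balancing
#' class counts against the proportional target).
#'
#' @param d an `autosig_dataset`
#' @param K fold count (at most the rarest class count)
#' @param seed integer seed
#' @return integer vector of fold ids in 1..K
#' @export
build_folds <- function(d, K, seed) {
  n <- n_samples(d)
  if (is.null(d$group_ids)) {
    folds <- integer(n)
    with_seed(seed, {
      for (ci in seq_along(levels(d$outcome))) {
        rows <- which(d$outcome == levels(d$outcome)[ci])
        ids <- rep(seq_len(K), length.out = length(rows))
        ids <- ((ids - 1L + (ci - 1L)) %% K) + 1L  # rotate start across classes
        folds[sample(rows)] <- ids
      }
    })
    folds
  } else {
    build_group_folds(d, K, seed)
  }
}

build_group_folds <- function(d, K, seed) {
  groups <- split(seq_len(n_samples(d)), d$group_ids)
  target <- as.numeric(table(d$outcome)) / K  # per-fold class target
  folds <- integer(n_samples(d))
  counts <- matrix(0, K, length(levels(d$outcome)))
  with_seed(seed, {
    ord <- order(-lengths(groups) + stats::runif(length(groups)) * 0.5)
    for (g in groups[ord]) {
      cls <- as.numeric(table(factor(d$outcome[g], levels = levels(d$outcome))))
      dev <- vapply(seq_len(K), function(k)
        sum(abs(counts[k, ] + cls - target)), numeric(1))
      k <- which.min(dev)
      folds[g] <- k
      counts[k, ] <- counts[k, ] + cls
    }
  })
  folds
}

# fit one configuration on the training rows and predict the test rows;
# pre/selector caches are shared across configurations within a fold
fit_predict_config <- function(conf, pre, sel_cache, ytr, positive, test_mat, seed) {
  feats <- selector_features(conf$selector, pre, ytr, sel_cache)
  if (length(feats) == 0L) {
    # empty signature: nothing to model, fall back to the class prior
    clf <- fit_classifier("baseline_majority", list(),
                          matrix(0, length(ytr), 0L), ytr, positive, seed)
    return(list(pred = predict_proba(clf, matrix(0, nrow(test_mat), 0L)),
                n_features = 0L))
  }
  Xtr <- pre$train[, feats, drop = FALSE]
  clf <- fit_classifier(conf$classifier$family, conf$classifier$hyper,
                        Xtr, ytr, positive, seed)
  list(pred = predict_proba(clf, test_mat[, feats, drop = FALSE]),
       n_features = length(feats))
}

selector_features <- function(sel, pre, ytr, cache) {
  key <- switch(sel$kind,
    none = "none",
    ses = sprintf("ses|%g|%d|%d", sel$params$alpha, sel$params$maxk,
                  sel$params$max_features %||% 25L),
    lasso = sprintf("lasso|%g|%d", sel$params$penalty,
                    sel$params$max_features %||% 25L))
  if (!is.null(cache[[key]])) return(cache[[key]])
  feats <- switch(sel$kind,
    none = colnames(pre$train),
    ses = primary_signature(ses_select(
      pre$train, ytr, alpha = sel$params$alpha, maxk = sel$params$maxk,
      max_features = sel$params$max_features %||% 25L)),
    lasso = primary_signature(lasso_select(
      pre$train, ytr, penalty = sel$params$penalty,
      max_features = sel$params$max_features %||% 25L)))
  cache[[key]] <- feats
  feats
}

#' Run the GCV protocol over a configuration space
#'
#' For each repeat and each of the first N folds, every surviving
#' configuration's full pipeline is fitted on the training folds and scored
#' on the held-out fold; held-out predictions are pooled into the
#' out-of-sample matrix. Between fold rounds the Early Dropping test can
#' abandon configurations unlikely to win; between repeats Early Stopping
#' can end the run when the winner's confidence interval stops shrinking. A
#' configuration that errors on any fold is marked failed and excluded.
#'
#' @param d an `autosig_dataset`.
#' @param configs list of `autosig_configuration`.
#' @param plan an `autosig_gcv_plan`.
#' @param dropping,stopping enable the heuristics.
#' @param alpha_drop one-sided level of the dropping test (drop when the
#'   bootstrap probability that the configuration beats the incumbent falls
#'   below it).
#' @param stop_tol relative CI-width shrinkage below which a further repeat
#'   is judged unprofitable.
#' @param min_drop_n minimum pooled predictions before dropping is allowed.
#' @param repeat_offset shifts the internal repeat index used to derive
#'   fold and classifier seeds; lets a single-repeat rerun reproduce the
#'   partitions of repeat `repeat_offset + 1` of a multi-repeat run.
#' @return object of class `autosig_oos`: `predictions` (rows =
#'   held-out (sample, repeat) pairs, columns = configurations), `labels`,
#'   `positive`, `sample_idx`, `repeat_idx`, `config_ids`, `dropped`,
#'   `drop_round`, `failed`, `completed_repeats`, `pooled_auc`,
#'   `n_features`, `fold_auc`, `plan`.
#' @export
run_gcv <- function(d, configs, plan, dropping = FALSE, stopping = FALSE,
                    alpha_drop = 0.01, stop_tol = 0.05, min_drop_n = 50L,
                    repeat_offset = 0L) {
  n <- n_samples(d)
  C <- length(configs)
  ids <- vapply(configs, `[[`, character(1), "id")
  alive <- rep(TRUE, C); failed <- rep(FALSE, C)
  drop_round <- rep(NA_integer_, C)
  last_tested_n <- rep(0L, C)   # pooled size at each config's last drop test
  nfeat_sum <- numeric(C); nfeat_cnt <- integer(C)
  fold_auc <- list()
  pred_rows <- list(); lab_rows <- list(); samp_rows <- list(); rep_rows <- list()
  ci_widths <- numeric(0)
  completed <- 0L
  round_idx <- 0L

  for (r in seq_len(plan$R)) {
    rr <- r + repeat_offset
    folds <- build_folds(d, plan$K, derive_seed(plan$seed, rr - 1L))
    for (k in seq_len(plan$N)) {
      round_idx <- round_idx + 1L
      test_idx <- which(folds == k)
      train_idx <- which(folds != k)
      ytr <- d$outcome[train_idx]
      pre <- fit_preprocess(d$values[train_idx, , drop = FALSE])
      test_mat <- apply_preprocess(pre$chain, d$values[test_idx, , drop = FALSE])
      sel_cache <- new.env(parent = emptyenv())
      preds_k <- matrix(NA_real_, length(test_idx), C)
      for (ci in which(alive)) {
        res <- tryCatch(
          fit_predict_config(configs[[ci]], pre, sel_cache, ytr, d$positive,
                             test_mat, derive_seed(plan$seed, rr * 10000L + k * 100L + ci)),
          error = function(e) NULL)
        if (is.null(res)) {
          alive[ci] <- FALSE; failed[ci] <- TRUE
          next
        }
        preds_k[, ci] <- res$pred
        nfeat_sum[ci] <- nfeat_sum[ci] + res$n_features
        nfeat_cnt[ci] <- nfeat_cnt[ci] + 1L
        fold_auc[[length(fold_auc) + 1L]] <-
          list(config = ids[ci], rep = r, fold = k,
               auc = auc(res$pred, d$outcome[test_idx], positive = d$positive))
      }
      pred_rows[[round_idx]] <- preds_k
      lab_rows[[round_idx]] <- d$outcome[test_idx]
      samp_rows[[round_idx]] <- test_idx
      rep_rows[[round_idx]] <- rep(r, length(test_idx))

      if (dropping && sum(alive) > 1L) {
        P <- do.call(rbind, pred_rows)
        y_all <- factor(unlist(lapply(lab_rows, as.character)),
                        levels = levels(d$outcome))
        if (nrow(P) >= min_drop_n) {
          pooled <- vapply(seq_len(C), function(ci)
            if (alive[ci]) auc(P[, ci], y_all, positive = d$positive) else -Inf,
            numeric(1))
          b <- which.max(pooled)
          for (ci in which(alive)) {
            if (ci == b) next
            # near-incumbent challengers trivially survive (P ~ 0.5); others
            # are retested only once their pooled evidence grew by >= 30%
            if (pooled[ci] >= pooled[b] - 0.01) next
            if (nrow(P) < ceiling(1.3 * last_tested_n[ci])) next
            last_tested_n[ci] <- nrow(P)
            if (early_drop(P[, ci], P[, b], y_all, positive = d$positive,
                           alpha_drop = alpha_drop,
                           seed = derive_seed(plan$seed, 555L + round_idx * 131L + ci))) {
              alive[ci] <- FALSE
              drop_round[ci] <- round_idx
            }
          }
        }
      }
    }
    completed <- r
    if (stopping && plan$R > 1L) {
      P <- do.call(rbind, pred_rows)
      y_all <- factor(unlist(lapply(lab_rows, as.character)),
                      levels = levels(d$outcome))
      pooled <- vapply(seq_len(C), function(ci)
        if (alive[ci]) auc(P[, ci], y_all, positive = d$positive) else -Inf,
        numeric(1))
      b <- which.max(pooled)
      ci_widths <- c(ci_widths, auc_ci_width(P[, b], y_all, d$positive,
                                             seed = derive_seed(plan$seed, 777L + r)))
      if (length(ci_widths) >= 2L && early_stop(ci_widths, stop_tol)) break
    }
  }

  P <- do.call(rbind, pred_rows)
  labels <- factor(unlist(lapply(lab_rows, as.character)), levels = levels(d$outcome))
  colnames(P) <- ids
  pooled_auc <- vapply(seq_len(C), function(ci) {
    ok <- !is.na(P[, ci])
    if (!any(ok)) return(NA_real_)
    auc(P[ok, ci], labels[ok], positive = d$positive)
  }, numeric(1))
  structure(list(
    predictions = P, labels = labels, positive = d$positive,
    sample_idx = unlist(samp_rows), repeat_idx = unlist(rep_rows),
    config_ids = ids,
    dropped = !alive & !failed, drop_round = drop_round, failed = failed,
    completed_repeats = completed,
    pooled_auc = pooled_auc,
    n_features = ifelse(nfeat_cnt > 0, nfeat_sum / pmax(nfeat_cnt, 1L), NA_real_),
    fold_auc = fold_auc, ci_widths = ci_widths, plan = plan
  ), class = "autosig_oos")
}

#' @export
print.autosig_oos <- function(x, ...) {
  cat(sprintf("<autosig_oos> %d held-out predictions x %d configurations (%d dropped, %d failed), %d repeat(s)\n",
              nrow(x$predictions), ncol(x$predictions), sum(x$dropped),
              sum(x$failed), x$completed_repeats))
  invisible(x)
}

# percentile-bootstrap width of the pooled-AUC 95% CI
auc_ci_width <- function(pred, labels, positive, B = 200L, seed = 1L) {
  n <- length(pred)
  with_seed(seed, {
    stats_b <- vapply(seq_len(B), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[i])) < 2L) return(NA_real_)
      auc(pred[i], labels[i], positive = positive)
    }, numeric(1))
    q <- stats::quantile(stats_b, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    q[2] - q[1]
  })
}

#' Early-dropping decision
#'
#' One-sided bootstrap test on the pooled out-of-sample predictions: the
#' challenger is dropped when the bootstrap estimate of
#' P(AUC_challenger >= AUC_incumbent) falls below `alpha_drop`.
#'
#' @param pred_c,pred_b pooled predictions of challenger and incumbent.
#' @param labels aligned outcome factor.
#' @param positive positive class level.
#' @param alpha_drop drop threshold (default 0.01).
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @return TRUE to drop the challenger, FALSE to keep it.
#' @export
early_drop <- function(pred_c, pred_b, labels, positive,
                       alpha_drop = 0.01, B = 300L, seed = 1L) {
  ok <- !is.na(pred_c) & !is.na(pred_b)
  pred_c <- pred_c[ok]; pred_b <- pred_b[ok]; labels <- labels[ok]
  n <- length(pred_c)
  if (n < 2L) return(FALSE)
  wins <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[i])) < 2L) return(NA)
      auc(pred_c[i], labels[i], positive) >= auc(pred_b[i], labels[i], positive)
    }, logical(1))
  })
  mean(wins, na.rm = TRUE) < alpha_drop
}

#' Early-stopping decision
#'
#' Stops further CV repeats when the winner's confidence interval stopped
#' shrinking: relative width reduction from the previous repeat below
#' `tolerance`.
#'
#' @param widths numeric vector of CI widths, one per completed repeat.
#' @param tolerance relative-shrinkage threshold (default 0.05).
#' @return TRUE to stop, FALSE to continue.
#' @export
early_stop <- function(widths, tolerance = 0.05) {
  m <- length(widths)
  if (m < 2L) return(FALSE)
  prev <- widths[m - 1L]
  if (prev <= 0) return(TRUE)
  (prev - widths[m]) / prev < tolerance
}

#' Persist the out-of-sample matrix
#'
#' Long-format gzip-compressed CSV: sample index, repeat, configuration id,
#' prediction, label.
#' @param oos an `autosig_oos`
#' @param path output path (".csv.gz")
#' @export
write_oos <- function(oos, path) {
  C <- ncol(oos$predictions)
  long <- data.frame(
    sample = rep(oos$sample_idx, C),
    rep = rep(oos$repeat_idx, C),
    config = rep(oos$config_ids, each = nrow(oos$predictions)),
    prediction = as.vector(oos$predictions),
    label = rep(as.character(oos$labels), C)
  )
  con <- gzfile(path, "w")
  on.exit(close(con))
  utils::write.csv(long[!is.na(long$prediction), ], con, row.names = FALSE)
  invisible(path)
}
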