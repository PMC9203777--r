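# Permutation tests for comparing two analysis runs' holdout performances
# and for testing whether an estimation bias is centered at zero. Both are
# median-based, two-tailed, with the add-one finite-permutation correction
# so a p-value is never exactly zero.

row_medians <- function(m) {
  if (is.null(dim(m))) return(stats::median(m))
  apply(m, 1L, stats::median)
}

#' Exchange permutation test for paired performance vectors
#'
#' Tests whether two tools' holdout performances over the same runs differ:
#' the statistic is the median of the paired differences; its null
#' distribution is built by exchanging each pair's two values with
#' probability 1/2 and recomputing the median.
#'
#' @param auc_1,auc_2 aligned performance vectors over the runs both tools
#'   completed.
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @return list of class `autosig_permtest`: `statistic` (observed median
#'   difference), `p_value` (two-tailed, add-one corrected), `n_perm`.
#' @export
exchange_test <- function(auc_1, auc_2, n_perm = 10000L, seed = 1L) {
  stopifnot(length(auc_1) == length(auc_2), n_perm >= 1L)
  if (length(auc_1) == 0L) abort_autosig("empty_vectors", "no paired runs")
  d <- auc_1 - auc_2
  M <- stats::median(d)
  perm_m <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE),
                    n_perm, length(d))
    row_medians(signs * rep(d, each = n_perm))
  })
  p <- (sum(abs(perm_m) >= abs(M)) + 1) / (n_perm + 1)
  structure(list(statistic = M, p_value = p, n_perm = as.integer(n_perm),
                 test = "exchange"),
            class = "autosig_permtest")
}

#' Sign-flip test for estimation bias
#'
#' Tests whether per-run bias values (holdout performance minus
#' training-derived estimate) are symmetrically centered at zero: the
#' statistic is their median; the null distribution flips each sign with
#' probability 1/2.
#'
#' @param b numeric vector of per-run bias values.
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @return `autosig_permtest` as in [exchange_test()].
#' @export
signflip_bias_test <- function(b, n_perm = 10000L, seed = 1L) {
  stopifnot(n_perm >= 1L)
  if (length(b) == 0L) abort_autosig("empty_vectors", "no bias values")
  if (!all(is.finite(b))) abort_autosig("bad_input", "bias values must be finite")
  M <- stats::median(b)
  perm_m <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * length(b), replace = TRUE),
                    n_perm, length(b))
    row_medians(signs * rep(b, each = n_perm))
  })
  p <- (sum(abs(perm_m) >= abs(M)) + 1) / (n_perm + 1)
  structure(list(statistic = M, p_value = p, n_perm = as.integer(n_perm),
                 test = "signflip"),
            class = "autosig_permtest")
}

#' @export
print.autosig_permtest <- function(x, ...) {
  cat(sprintf("<autosig_permtest:%s> median = %.4f, p = %.4g (%d permutations)\n",
              x$test, x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Bonferroni adjustment for a family of comparisons
#'
#' @param p vector of raw p-values.
#' @param m family size (defaults to `length(p)`).
#' @return adjusted p-values, capped at 1.
#' @export
bonferroni_adjust <- function(p, m = length(p)) pmin(1, p * m)
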