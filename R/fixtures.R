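# Synthetic data generator: Gaussian feature blocks, logistic outcome with
# intercept calibrated to a target minority fraction, planted equivalent
# feature copies, completely-at-random missingness. Every downstream module
# is testable on these tables without any external download.

#' Specify a synthetic dataset
#'
#' @param n sample count.
#' @param p feature count (informative block + planted duplicates + noise).
#' @param k_informative number of features carrying signal (0 gives a null
#'   dataset whose outcome is independent of every feature).
#' @param effect_sizes logistic coefficients for the informative block;
#'   recycled to length `k_informative`.
#' @param duplicate_map data.frame with columns `source` (index into the
#'   informative block) and `sd` (noise standard deviation of the planted
#'   copy; 0 gives an exact copy). Each duplicate occupies one of the `p`
#'   columns after the informative block.
#' @param correlation within-informative-block correlation in [0,1).
#' @param minority_fraction target minority-class fraction in (0, 0.5].
#' @param missing_fraction completely-at-random missing-cell fraction in [0,1).
#' @param seed integer seed; the same spec is byte-identical across calls.
#' @return list of class `autosig_fixture_spec`.
#' @export
fixture_spec <- function(n, p, k_informative = 0L,
                         effect_sizes = 1,
                         duplicate_map = NULL,
                         correlation = 0,
                         minority_fraction = 0.5,
                         missing_fraction = 0,
                         seed = 1L) {
  n_dup <- if (is.null(duplicate_map)) 0L else nrow(duplicate_map)
  if (k_informative > p)
    abort_autosig("infeasible_fixture", "k_informative exceeds p")
  if (k_informative + n_dup > p)
    abort_autosig("infeasible_fixture", "informative block plus duplicates exceed p")
  if (n_dup > 0 && any(duplicate_map$source > k_informative))
    abort_autosig("infeasible_fixture", "duplicates must copy informative features")
  stopifnot(correlation >= 0, correlation < 1,
            minority_fraction > 0, minority_fraction <= 0.5,
            missing_fraction >= 0, missing_fraction < 1,
            minority_fraction * n >= 2)
  structure(list(
    n = as.integer(n), p = as.integer(p), k_informative = as.integer(k_informative),
    effect_sizes = if (k_informative > 0) rep_len(effect_sizes, k_informative) else numeric(0),
    duplicate_map = duplicate_map, correlation = correlation,
    minority_fraction = minority_fraction, missing_fraction = missing_fraction,
    seed = as.integer(seed)
  ), class = "autosig_fixture_spec")
}

#' Generate a synthetic dataset with known ground truth
#'
#' Continuous features are correlated Gaussians (a shared factor within the
#' informative block); the outcome is Bernoulli under a logistic model on
#' the informative block, with the intercept found by bisection so that the
#' expected minority ("pos") fraction matches the spec to within 0.01.
#' Planted duplicates are source + Gaussian noise.
#'
#' @param spec an [fixture_spec()] object.
#' @return list with `dataset` (an `autosig_dataset`, outcome levels
#'   `neg`/`pos` with `pos` the minority and positive class) and `truth`
#'   (list: `informative` feature names, `equivalence` classes of planted
#'   duplicates, `beta`, `intercept`).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "autosig_fixture_spec"))
  with_seed(spec$seed, {
    k <- spec$k_informative
    n_dup <- if (is.null(spec$duplicate_map)) 0L else nrow(spec$duplicate_map)
    n_noise <- spec$p - k - n_dup
    X <- matrix(stats::rnorm(spec$n * spec$p), spec$n, spec$p)
    if (k > 1 && spec$correlation > 0) {
      shared <- stats::rnorm(spec$n)
      X[, seq_len(k)] <- sqrt(spec$correlation) * shared +
        sqrt(1 - spec$correlation) * X[, seq_len(k)]
    }
    if (n_dup > 0) {
      for (i in seq_len(n_dup)) {
        src <- spec$duplicate_map$source[i]
        sd <- spec$duplicate_map$sd[i]
        X[, k + i] <- X[, src] + if (sd > 0) stats::rnorm(spec$n, sd = sd) else 0
      }
    }
    eta <- if (k > 0) drop(X[, seq_len(k), drop = FALSE] %*% spec$effect_sizes) else
      numeric(spec$n)
    icpt <- calibrate_intercept(eta, spec$minority_fraction)
    pr <- stats::plogis(icpt + eta)
    y <- factor(ifelse(stats::runif(spec$n) < pr, "pos", "neg"), levels = c("neg", "pos"))
    # guard degenerate draws on tiny n: flip cells until both classes have 2
    for (lv in c("pos", "neg")) {
      while (sum(y == lv) < 2L) {
        other <- which(y != lv)
        y[other[which.max(if (lv == "pos") pr[other] else -pr[other])]] <- lv
      }
    }
    fnames <- sprintf("f%03d", seq_len(spec$p))
    values <- as.data.frame(X)
    colnames(values) <- fnames
    d <- new_dataset(values, y, positive = "pos")
    if (spec$missing_fraction > 0)
      d <- inject_missing(d, spec$missing_fraction, seed = derive_seed(spec$seed, 1L))
    equivalence <- NULL
    if (n_dup > 0) {
      equivalence <- lapply(split(seq_len(n_dup), spec$duplicate_map$source),
                            function(ii) c(fnames[spec$duplicate_map$source[ii[1]]],
                                           fnames[k + ii]))
      names(equivalence) <- NULL
    }
    list(dataset = d,
         truth = list(informative = if (k > 0) fnames[seq_len(k)] else character(0),
                      equivalence = equivalence,
                      beta = spec$effect_sizes, intercept = icpt))
  })
}

# bisection on the intercept so mean plogis(c + eta) hits the target
calibrate_intercept <- function(eta, target, tol = 0.01) {
  f <- function(c0) mean(stats::plogis(c0 + eta)) - target
  lo <- -50; hi <- 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) <= tol / 2) return(mid)
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  mid
}

#' Insert completely-at-random missing cells
#'
#' Each feature cell is set missing independently with the given
#' probability; the outcome is never touched.
#' @param d an `autosig_dataset`
#' @param fraction missing probability per cell, in [0,1)
#' @param seed integer seed
#' @return the dataset with missing cells inserted
#' @export
inject_missing <- function(d, fraction, seed) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(d)
  with_seed(seed, {
    n <- n_samples(d); p <- n_features(d)
    mask <- matrix(stats::runif(n * p) < fraction, n, p)
    for (j in seq_len(p)) d$values[mask[, j], j] <- NA
    d
  })
}
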