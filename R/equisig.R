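# Feature selection. ses_select() is a forward-backward selection driven
# by conditional-independence tests, in the Markov-blanket tradition: it
# admits the most dependent candidate, detects candidates that are
# statistically interchangeable with it (equivalence classes), and prunes
# features that become independent of the outcome given the rest. The
# result is one or many statistically equivalent minimal signatures.
# lasso_select() is the single-signature alternative via glmnet.

#' Conditional-independence test for a binary outcome
#'
#' Likelihood-ratio test between nested logistic regressions
#' `y ~ conditioning` and `y ~ conditioning + X_j`, referred to a
#' chi-squared distribution with degrees of freedom equal to the gain in
#' model rank. A constant candidate (or one aliased with the conditioning
#' set) contributes no rank and returns p = 1 by convention.
#'
#' @param X numeric feature matrix.
#' @param y binary factor or 0/1 vector.
#' @param j candidate column index.
#' @param cond integer vector of conditioning column indices (may be empty);
#'   must exclude `j`.
#' @return p-value in [0,1]; deterministic.
#' @export
cond_independence_test <- function(X, y, j, cond = integer(0)) {
  stopifnot(!j %in% cond)
  n <- nrow(X)
  if (n <= length(cond) + 2L)
    abort_autosig("too_few_samples", "need n > |conditioning set| + 2")
  ybin <- if (is.factor(y)) as.numeric(y == levels(y)[2]) else as.numeric(y)
  xj <- X[, j]
  if (stats::sd(xj) < 1e-12) return(1)
  f0 <- logistic_dev(cbind(1, X[, cond, drop = FALSE]), ybin)
  f1 <- logistic_dev(cbind(1, X[, c(cond, j), drop = FALSE]), ybin)
  df <- f1$rank - f0$rank
  if (df <= 0L) return(1)
  stat <- max(f0$deviance - f1$deviance, 0)
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

logistic_dev <- function(Xmat, ybin) {
  fit <- suppressWarnings(
    stats::glm.fit(Xmat, ybin, family = stats::binomial(),
                   control = stats::glm.control(maxit = 50)))
  list(deviance = fit$deviance, rank = fit$rank)
}

#' Multiple statistically-equivalent signature selection
#'
#' Forward phase: iteratively admit the candidate with the smallest
#' maximal conditional p-value below `alpha`, maximizing over conditioning
#' subsets of the selected set up to size `maxk`. At each admission of a
#' feature f, any still-admissible candidate g that passes the symmetric
#' swap test — g independent of y given the selected set including f, AND
#' f independent of y given the selected set with g substituted for f,
#' both at level `alpha` — joins f's equivalence class and leaves the
#' candidate pool. Backward phase: a selected feature independent of y
#' given some subset (up to `maxk`) of the remaining selected features is
#' removed together with its class. Testing stops early when
#' `test_budget` independence tests have been spent (result flagged
#' `truncated`).
#'
#' @param X numeric feature matrix with column names.
#' @param y binary factor outcome.
#' @param alpha significance level of the conditional-independence test.
#' @param maxk maximum conditioning-subset size.
#' @param max_features cap on signature size (default 25).
#' @param test_budget maximum number of independence tests.
#' @param max_enumerate cap on explicitly enumerated signatures; the
#'   equivalence classes are always reported in full.
#' @return object of class `autosig_signature_set`: `equivalence_classes`
#'   (list of character vectors, position i = interchangeable choices for
#'   slot i), `signatures` (enumerated character matrices, possibly
#'   truncated), `n_signatures`, `truncated`, `n_tests`.
#' @export
ses_select <- function(X, y, alpha = 0.05, maxk = 3L, max_features = 25L,
                       test_budget = 50000L, max_enumerate = 10000L) {
  stopifnot(alpha > 0, alpha < 1, maxk >= 0, max_features >= 1)
  p <- ncol(X)
  budget <- new.env(parent = emptyenv())
  budget$left <- as.integer(test_budget)
  budget$truncated <- FALSE
  test <- function(j, cond) {
    if (budget$left <= 0L) { budget$truncated <- TRUE; return(NA_real_) }
    budget$left <- budget$left - 1L
    cond_independence_test(X, y, j, cond)
  }

  candidates <- which(apply(X, 2, stats::sd) > 1e-12)
  selected <- integer(0)
  classes <- list()          # classes[[i]]: equivalence class of selected[i]
  maxp <- rep(NA_real_, p)
  for (j in candidates) {
    pv <- test(j, integer(0))
    if (is.na(pv)) break
    maxp[j] <- pv
  }
  candidates <- candidates[!is.na(maxp[candidates]) & maxp[candidates] < alpha]

  while (!budget$truncated && length(candidates) > 0L &&
         length(selected) < max_features) {
    f <- candidates[which.min(maxp[candidates])]
    selected <- c(selected, f)
    classes[[length(selected)]] <- f
    candidates <- setdiff(candidates, f)

    # equivalence scan: symmetric swap test against the newest feature
    for (g in candidates) {
      p1 <- test(g, selected)                                  # g | selected (incl f)
      if (is.na(p1)) break
      if (p1 < alpha) next
      p2 <- test(f, c(setdiff(selected, f), g))                # f | selected\{f} + g
      if (is.na(p2)) break
      if (p2 >= alpha) {
        classes[[length(selected)]] <- c(classes[[length(selected)]], g)
        candidates <- setdiff(candidates, g)
        maxp[g] <- NA_real_
      }
    }

    # update the running max p-value with subsets containing the new feature
    others <- setdiff(selected, f)
    subs <- cond_subsets(others, maxk - 1L)
    for (g in candidates) {
      for (s in subs) {
        pv <- test(g, c(s, f))
        if (is.na(pv)) break
        maxp[g] <- max(maxp[g], pv)
        if (maxp[g] >= alpha) break
      }
      if (budget$truncated) break
    }
    candidates <- candidates[maxp[candidates] < alpha]
  }

  # backward phase: drop features independent given a subset of the rest
  if (!budget$truncated && length(selected) > 1L) {
    for (f in selected) {
      others <- setdiff(selected, f)
      subs <- cond_subsets(others, maxk)
      subs <- subs[lengths(subs) > 0L]
      gone <- FALSE
      for (s in subs) {
        pv <- test(f, s)
        if (is.na(pv)) break
        if (pv >= alpha) { gone <- TRUE; break }
      }
      if (gone) {
        kidx <- which(selected == f)
        selected <- selected[-kidx]
        classes <- classes[-kidx]
      }
      if (budget$truncated) break
    }
  }

  class_names <- lapply(classes, function(ix) colnames(X)[ix])
  new_signature_set(class_names, max_enumerate = max_enumerate,
                    truncated = budget$truncated,
                    n_tests = as.integer(test_budget) - budget$left)
}

# all subsets of v with size 0..k (v indexed positionally: combn(scalar, .)
# would enumerate 1:scalar)
cond_subsets <- function(v, k) {
  k <- max(min(k, length(v)), 0L)
  out <- list(integer(0))
  if (k >= 1L) for (m in seq_len(k))
    out <- c(out, lapply(utils::combn(seq_along(v), m, simplify = FALSE),
                         function(ix) v[ix]))
  out
}

new_signature_set <- function(equivalence_classes, max_enumerate = 10000L,
                              truncated = FALSE, n_tests = NA_integer_) {
  sizes <- lengths(equivalence_classes)
  n_sig <- if (length(sizes) == 0L) 0L else prod(sizes)
  sigs <- if (n_sig == 0L) list() else {
    n_keep <- min(n_sig, max_enumerate)
    grid <- expand.grid(equivalence_classes, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)[seq_len(n_keep), , drop = FALSE]
    lapply(seq_len(nrow(grid)), function(i) unname(unlist(grid[i, ])))
  }
  structure(list(equivalence_classes = equivalence_classes,
                 signatures = sigs,
                 n_signatures = n_sig,
                 enumeration_truncated = n_sig > length(sigs),
                 truncated = truncated,
                 n_tests = n_tests),
            class = "autosig_signature_set")
}

#' @export
print.autosig_signature_set <- function(x, ...) {
  cat(sprintf("<autosig_signature_set> %d signature(s) of size %d%s\n",
              x$n_signatures, length(x$equivalence_classes),
              if (x$truncated) " [test budget exhausted]" else ""))
  for (i in seq_along(x$equivalence_classes))
    cat(sprintf("  slot %d: {%s}\n", i,
                paste(x$equivalence_classes[[i]], collapse = ", ")))
  invisible(x)
}

#' Primary signature of a signature set
#'
#' The first member of each equivalence class (the admitted representative).
#' @param s an `autosig_signature_set`
#' @return character vector of feature names (possibly empty)
#' @export
primary_signature <- function(s) {
  vapply(s$equivalence_classes, `[[`, character(1), 1L)
}

#' LASSO single-signature selection
#'
#' Features with nonzero coefficients in an L1-penalized logistic
#' regression at a fixed penalty. One signature per penalty value; the
#' penalty is a configuration hyper-parameter upstream.
#'
#' @param X numeric feature matrix with column names (expected standardized
#'   by the pipeline; no internal standardization).
#' @param y binary factor outcome.
#' @param penalty nonnegative L1 penalty (glmnet lambda).
#' @param max_features optional cap: if more coefficients are nonzero, the
#'   largest in absolute value are kept.
#' @return `autosig_signature_set` with a single signature.
#' @export
lasso_select <- function(X, y, penalty, max_features = Inf) {
  ybin <- as.numeric(y == levels(factor(y))[2])
  Xe <- X
  if (ncol(Xe) < 2L) Xe <- cbind(Xe, `.pad` = 0)
  fit <- glmnet::glmnet(Xe, ybin, family = "binomial", alpha = 1,
                        lambda = penalty, standardize = FALSE,
                        thresh = 1e-9, maxit = 1e6)
  cf <- as.matrix(stats::coef(fit, s = penalty))[-1, 1]
  cf <- cf[names(cf) %in% colnames(X)]
  nz <- cf[cf != 0]
  if (length(nz) > max_features)
    nz <- nz[order(abs(nz), decreasing = TRUE)][seq_len(max_features)]
  keep <- names(nz)[order(match(names(nz), colnames(X)))]
  new_signature_set(as.list(keep))
}
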