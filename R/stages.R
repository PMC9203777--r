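# Pipeline stages: preprocessing transforms and classifiers. Every stage
# obeys a strict fit-on-training-only contract: apply() uses the fitted
# state, never statistics of the data it is applied to. Pipelines are
# evaluated as atoms downstream, so no stage may peek outside its fold.

TRANSFORM_KINDS <- c("constant_removal", "mean_mode_impute", "one_hot", "standardize")

CLASSIFIER_FAMILIES <- c("baseline_majority", "decision_tree", "ridge_logistic",
                         "random_forest", "svm_linear", "svm_poly", "svm_rbf")

#' Fit a preprocessing transform on training data
#'
#' Kinds: `constant_removal` drops columns whose non-missing values are
#' constant (variance at machine-epsilon scale); `mean_mode_impute` stores
#' the per-column training mean (continuous) or mode (categorical);
#' `one_hot` stores the observed category levels of each categorical column
#' (encoding is one indicator per observed level, so an unseen level maps
#' to all zeros); `standardize` stores training mean and sd of each
#' continuous column.
#'
#' @param kind one of `r paste(TRANSFORM_KINDS, collapse=", ")`.
#' @param train data.frame of training features.
#' @return object of class `autosig_transform`.
#' @export
fit_transform <- function(kind, train) {
  kind <- match.arg(kind, TRANSFORM_KINDS)
  if (nrow(train) == 0L) abort_autosig("empty_table", "cannot fit on an empty table")
  state <- switch(kind,
    constant_removal = {
      keep <- vapply(train, function(col) {
        obs <- col[!is.na(col)]
        if (length(obs) == 0L) return(FALSE)
        if (is.numeric(obs)) stats::var(obs) > .Machine$double.eps * 100 &&
          !is.na(stats::var(obs)) else length(unique(obs)) > 1L
      }, logical(1))
      list(keep = names(train)[keep])
    },
    mean_mode_impute = {
      fills <- lapply(train, function(col) {
        obs <- col[!is.na(col)]
        if (is.numeric(col)) {
          if (length(obs) == 0L) 0 else mean(obs)
        } else {
          if (length(obs) == 0L) "missing" else names(sort(table(obs), decreasing = TRUE))[1]
        }
      })
      list(fills = fills)
    },
    one_hot = {
      cats <- names(train)[!vapply(train, is.numeric, logical(1))]
      list(levels = lapply(stats::setNames(cats, cats),
                           function(nm) sort(unique(train[[nm]][!is.na(train[[nm]])]))))
    },
    standardize = {
      num <- names(train)[vapply(train, is.numeric, logical(1))]
      sds <- vapply(num, function(nm) stats::sd(train[[nm]], na.rm = TRUE), numeric(1))
      if (any(!is.finite(sds) | sds <= .Machine$double.eps * 100))
        abort_autosig("zero_variance",
                      "standardize hit a zero-variance column; run constant_removal first")
      list(mean = vapply(num, function(nm) mean(train[[nm]], na.rm = TRUE), numeric(1)),
           sd = sds)
    })
  structure(list(kind = kind, state = state, schema = names(train)),
            class = "autosig_transform")
}

#' Apply a fitted transform
#'
#' Uses only the state learned at fit time. The input must have the same
#' columns as the fit-time table.
#' @param t an `autosig_transform`
#' @param tbl data.frame with the fit-time schema
#' @return transformed data.frame
#' @export
apply_transform <- function(t, tbl) {
  stopifnot(inherits(t, "autosig_transform"))
  if (!identical(names(tbl), t$schema))
    abort_autosig("schema_mismatch", "columns differ from the fit-time schema")
  switch(t$kind,
    constant_removal = tbl[, t$state$keep, drop = FALSE],
    mean_mode_impute = {
      for (nm in names(tbl)) {
        miss <- is.na(tbl[[nm]])
        if (any(miss)) tbl[[nm]][miss] <- t$state$fills[[nm]]
      }
      tbl
    },
    one_hot = {
      out <- tbl
      for (nm in names(t$state$levels)) {
        levs <- t$state$levels[[nm]]
        block <- vapply(levs, function(lv) as.numeric(!is.na(tbl[[nm]]) & tbl[[nm]] == lv),
                        numeric(nrow(tbl)))
        block <- matrix(block, nrow = nrow(tbl),
                        dimnames = list(NULL, paste0(nm, "=", levs)))
        out[[nm]] <- NULL
        out <- cbind(out, as.data.frame(block, check.names = FALSE))
      }
      out
    },
    standardize = {
      for (nm in names(t$state$mean))
        tbl[[nm]] <- (tbl[[nm]] - t$state$mean[[nm]]) / t$state$sd[[nm]]
      tbl
    })
}

# The canonical chain: constant_removal -> impute -> one_hot -> standardize.
# Returns fitted transforms plus the transformed training matrix.
fit_preprocess <- function(train) {
  chain <- list()
  cur <- train
  for (kind in TRANSFORM_KINDS) {
    tr <- fit_transform(kind, cur)
    cur <- apply_transform(tr, cur)
    chain[[kind]] <- tr
  }
  list(chain = chain, train = as.matrix(cur))
}

apply_preprocess <- function(chain, tbl) {
  for (tr in chain) tbl <- apply_transform(tr, tbl)
  as.matrix(tbl)
}

#' Fit a classifier
#'
#' Families: `baseline_majority` (predicts the training positive-class
#' frequency for every sample), `decision_tree` (rpart; hyper: `min_leaf`,
#' `criterion` in gini/information), `ridge_logistic` (glmnet, alpha 0;
#' hyper: `lambda`), `random_forest` (ranger; hyper: `num_trees`, `mtry`,
#' `min_leaf`), `svm_linear` / `svm_poly` / `svm_rbf` (e1071; hyper: `cost`,
#' `gamma`, `degree`). SVM probabilities come from a monotone logistic
#' calibration of the decision values, fitted on the training data.
#' Standardization is an explicit pipeline stage, so no family standardizes
#' internally. Single-class training data falls back to the baseline with a
#' warning.
#'
#' @param family one of the families above.
#' @param hyper named list of family-specific hyper-parameter values.
#' @param X numeric training matrix (post-preprocessing).
#' @param y factor outcome (2 levels).
#' @param positive the positive class level.
#' @param seed integer seed for the stochastic families.
#' @return object of class `autosig_classifier`.
#' @export
fit_classifier <- function(family, hyper, X, y, positive, seed = 1L) {
  family <- match.arg(family, CLASSIFIER_FAMILIES)
  y <- factor(y)
  if (length(unique(y)) < 2L && family != "baseline_majority") {
    warning("single-class training data; falling back to the baseline classifier")
    family <- "baseline_majority"
  }
  ybin <- as.numeric(y == positive)
  fit <- switch(family,
    baseline_majority = list(prior = mean(ybin)),
    decision_tree = {
      df <- data.frame(.y = factor(ybin), X, check.names = FALSE)
      with_seed(seed, rpart::rpart(
        .y ~ ., data = df, method = "class",
        parms = list(split = hyper$criterion %||% "gini"),
        control = rpart::rpart.control(minbucket = hyper$min_leaf %||% 3L,
                                       cp = 0.01, xval = 0)))
    },
    ridge_logistic = fit_glmnet_binomial(X, ybin, alpha = 0,
                                         lambda = hyper$lambda %||% 1),
    random_forest = {
      df <- data.frame(.y = factor(ybin), X, check.names = FALSE)
      ranger::ranger(
        dependent.variable.name = ".y", data = df, probability = TRUE,
        num.trees = hyper$num_trees %||% 500L,
        mtry = min(hyper$mtry %||% max(1L, floor(sqrt(ncol(X)))), ncol(X)),
        min.node.size = hyper$min_leaf %||% 1L,
        seed = seed, num.threads = 1L)
    },
    svm_linear = ,
    svm_poly = ,
    svm_rbf = fit_svm_calibrated(family, hyper, X, ybin, seed))
  structure(list(family = family, hyper = hyper, fit = fit,
                 positive = positive, levels = levels(y),
                 p = ncol(X), feature_names = colnames(X)),
            class = "autosig_classifier")
}

fit_glmnet_binomial <- function(X, ybin, alpha, lambda) {
  Xe <- X
  if (ncol(Xe) < 2L) Xe <- cbind(Xe, `.pad` = 0)  # glmnet needs >= 2 columns
  fit <- glmnet::glmnet(Xe, ybin, family = "binomial", alpha = alpha,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-10, maxit = 1e6)
  list(glmnet = fit, padded = ncol(X) < 2L, lambda = lambda)
}

fit_svm_calibrated <- function(family, hyper, X, ybin, seed) {
  kernel <- switch(family, svm_linear = "linear", svm_poly = "polynomial",
                   svm_rbf = "radial")
  sv <- with_seed(seed, e1071::svm(
    x = X, y = factor(ybin), kernel = kernel, scale = FALSE,
    cost = hyper$cost %||% 1,
    gamma = hyper$gamma %||% (1 / ncol(X)),
    degree = hyper$degree %||% 3L))
  dvm <- attr(stats::predict(sv, X, decision.values = TRUE), "decision.values")
  # orient decision values toward the positive (ybin = 1) class
  flip <- if (identical(colnames(dvm)[1], "0/1")) -1 else 1
  dv <- flip * drop(dvm)
  calib <- if (stats::sd(dv) < 1e-12) NULL else
    suppressWarnings(stats::glm.fit(cbind(1, dv), ybin,
                                    family = stats::binomial()))$coefficients
  list(svm = sv, flip = flip, calib = calib, prior = mean(ybin))
}

#' Predict positive-class probabilities
#'
#' @param c an `autosig_classifier`
#' @param X numeric matrix with the training schema
#' @return numeric vector in [0,1], one probability per row
#' @export
predict_proba <- function(c, X) {
  stopifnot(inherits(c, "autosig_classifier"))
  if (ncol(X) != c$p) abort_autosig("schema_mismatch", "feature count differs from fit time")
  pr <- switch(c$family,
    baseline_majority = rep(c$fit$prior, nrow(X)),
    decision_tree = {
      df <- as.data.frame(X, check.names = FALSE)
      p <- stats::predict(c$fit, df, type = "prob")
      if ("1" %in% colnames(p)) p[, "1"] else rep(0, nrow(X))
    },
    ridge_logistic = {
      Xe <- X
      if (c$fit$padded) Xe <- cbind(Xe, 0)
      drop(stats::predict(c$fit$glmnet, Xe, type = "response", s = c$fit$lambda))
    },
    random_forest = {
      df <- as.data.frame(X, check.names = FALSE)
      p <- stats::predict(c$fit, df, num.threads = 1L)$predictions
      if ("1" %in% colnames(p)) p[, "1"] else rep(0, nrow(X))
    },
    { # svm families
      if (is.null(c$fit$calib)) rep(c$fit$prior, nrow(X)) else {
        dv <- c$fit$flip *
          drop(attr(stats::predict(c$fit$svm, X, decision.values = TRUE),
                    "decision.values"))
        stats::plogis(c$fit$calib[1] + c$fit$calib[2] * dv)
      }
    })
  pmin(pmax(as.numeric(pr), 0), 1)
}
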