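# Tabular core: the Dataset container, CSV IO, meta-features, stratified
# splitting. Rows are samples, columns are measured features; one column
# carries the binary outcome and an optional column identifies grouped
# (correlated) samples that must never straddle a train/test boundary.

#' Default missing-value tokens
#'
#' Cell values (compared case-insensitively, after trimming) that are read
#' as missing: the empty string, "NA", "NaN" and "null" — the dialects most
#' omics exports use.
#' @export
default_missing_tokens <- function() c("", "na", "nan", "null")

#' Construct a Dataset
#'
#' @param values data.frame of n samples x p features. Continuous columns
#'   are numeric; categorical columns are character. Missing values are NA.
#' @param outcome factor of length n with exactly two observed levels and
#'   no missing entries.
#' @param group_ids optional vector of length n identifying clustered
#'   samples (e.g. repeated measurements of one subject).
#' @param positive optional outcome level to treat as the positive class;
#'   defaults to the lexicographically larger level so that AUC orientation
#'   is deterministic.
#' @return An object of class `autosig_dataset` with elements `values`,
#'   `outcome`, `feature_names`, `feature_kinds`, `group_ids`, `positive`.
#' @export
new_dataset <- function(values, outcome, group_ids = NULL, positive = NULL) {
  if (!is.data.frame(values)) abort_autosig("bad_input", "`values` must be a data.frame")
  if (nrow(values) == 0L || ncol(values) == 0L)
    abort_autosig("empty_table", "dataset has no samples or no features")
  if (anyNA(outcome)) abort_autosig("missing_outcome_values", "outcome contains missing entries")
  outcome <- factor(as.character(outcome))
  lev <- levels(outcome)
  if (length(lev) != 2L)
    abort_autosig("non_binary_outcome",
                  sprintf("outcome must have exactly 2 observed levels, found %d", length(lev)))
  if (length(outcome) != nrow(values))
    abort_autosig("bad_input", "outcome length does not match number of rows")
  cc <- table(outcome)
  if (any(cc < 2L))
    abort_autosig("class_too_small", "each outcome class needs at least 2 samples")
  if (!is.null(group_ids) && length(group_ids) != nrow(values))
    abort_autosig("bad_input", "group_ids length does not match number of rows")
  positive <- positive %||% max(lev)
  if (!positive %in% lev)
    abort_autosig("bad_input", sprintf("positive level '%s' not an outcome level", positive))
  kinds <- vapply(values, function(col) {
    if (is.numeric(col)) "continuous" else "categorical"
  }, character(1))
  values[] <- lapply(values, function(col) if (is.factor(col)) as.character(col) else col)
  structure(list(
    values = values,
    outcome = outcome,
    feature_names = colnames(values),
    feature_kinds = unname(kinds),
    group_ids = if (is.null(group_ids)) NULL else as.character(group_ids),
    positive = positive
  ), class = "autosig_dataset")
}

#' @export
print.autosig_dataset <- function(x, ...) {
  cat(sprintf("<autosig_dataset> %d samples x %d features\n", n_samples(x), n_features(x)))
  cat("  outcome:", paste(sprintf("%s=%d", names(table(x$outcome)), table(x$outcome)),
                          collapse = ", "),
      sprintf("(positive: %s)\n", x$positive))
  cat(sprintf("  kinds: %d continuous, %d categorical; missing cells: %d\n",
              sum(x$feature_kinds == "continuous"), sum(x$feature_kinds == "categorical"),
              sum(is.na(x$values))))
  if (!is.null(x$group_ids))
    cat(sprintf("  grouped samples: %d groups\n", length(unique(x$group_ids))))
  invisible(x)
}

#' @rdname new_dataset
#' @param d an `autosig_dataset`
#' @export
n_samples <- function(d) nrow(d$values)

#' @rdname new_dataset
#' @export
n_features <- function(d) ncol(d$values)

parse_numeric_quiet <- function(x) suppressWarnings(as.numeric(x))

#' Read a dataset from CSV
#'
#' Reads an RFC-4180 CSV with a mandatory header row, maps missing-value
#' tokens, sniffs column types (a column is continuous iff at least 90% of
#' its non-missing cells parse as numbers), and extracts the binary outcome
#' and optional group column by name.
#'
#' @param path CSV file path.
#' @param outcome_column name of the outcome column.
#' @param group_column optional name of the sample-group column.
#' @param missing_tokens character vector of tokens read as missing
#'   (case-insensitive; outcome and group cells are never mapped).
#' @param positive optional positive outcome level.
#' @return An `autosig_dataset`.
#' @export
read_dataset <- function(path, outcome_column, group_column = NULL,
                         missing_tokens = default_missing_tokens(),
                         positive = NULL) {
  if (!file.exists(path)) abort_autosig("file_not_found", paste("no such file:", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  if (nrow(raw) == 0L) abort_autosig("empty_table", "CSV has a header but no data rows")
  if (!outcome_column %in% colnames(raw))
    abort_autosig("missing_outcome_column",
                  sprintf("outcome column '%s' not found", outcome_column))
  outcome <- raw[[outcome_column]]
  if (any(trimws(outcome) == "" | tolower(trimws(outcome)) %in% missing_tokens))
    abort_autosig("missing_outcome_values", "outcome column contains missing entries")
  group_ids <- NULL
  drop <- outcome_column
  if (!is.null(group_column)) {
    if (!group_column %in% colnames(raw))
      abort_autosig("missing_group_column",
                    sprintf("group column '%s' not found", group_column))
    group_ids <- raw[[group_column]]
    drop <- c(drop, group_column)
  }
  feats <- raw[, setdiff(colnames(raw), drop), drop = FALSE]
  if (ncol(feats) == 0L) abort_autosig("empty_table", "no feature columns besides outcome")
  tok <- tolower(missing_tokens)
  feats[] <- lapply(feats, function(col) {
    col[tolower(trimws(col)) %in% tok] <- NA_character_
    col
  })
  feats[] <- lapply(feats, sniff_column)
  if (length(unique(outcome)) != 2L)
    abort_autosig("non_binary_outcome",
                  sprintf("outcome must have exactly 2 levels, found %d",
                          length(unique(outcome))))
  new_dataset(feats, outcome, group_ids = group_ids, positive = positive)
}

# continuous iff >= 90% of non-missing cells parse as numbers
sniff_column <- function(col) {
  obs <- col[!is.na(col)]
  if (length(obs) == 0L) return(parse_numeric_quiet(col))
  num <- parse_numeric_quiet(obs)
  if (mean(!is.na(num)) >= 0.9) parse_numeric_quiet(col) else col
}

#' Write a dataset back to CSV
#'
#' Inverse of [read_dataset()]: the written file, re-read with the same
#' outcome/group column names, reproduces values, kinds and outcome.
#' @param d an `autosig_dataset`
#' @param path output CSV path
#' @param outcome_column,group_column column names used in the file
#' @export
write_dataset <- function(d, path, outcome_column = "outcome",
                          group_column = "group") {
  out <- d$values
  out[[outcome_column]] <- as.character(d$outcome)
  if (!is.null(d$group_ids)) out[[group_column]] <- d$group_ids
  utils::write.csv(out, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Meta-features of a dataset
#'
#' The data characteristics (sample size, dimensionality, class balance,
#' missingness, feature types) that drive the choice of configuration space
#' and evaluation protocol.
#' @param d an `autosig_dataset`
#' @return list of class `autosig_meta` with fields `n`, `p`,
#'   `class_counts`, `rarest_class`, `imbalance_ratio`, `missing_fraction`,
#'   `n_categorical`, `n_constant`.
#' @export
compute_meta_features <- function(d) {
  cc <- as.integer(table(d$outcome))
  names(cc) <- levels(d$outcome)
  n_const <- sum(vapply(d$values, function(col) {
    obs <- col[!is.na(col)]
    length(unique(obs)) <= 1L
  }, logical(1)))
  structure(list(
    n = n_samples(d),
    p = n_features(d),
    class_counts = cc,
    rarest_class = min(cc),
    imbalance_ratio = min(cc) / n_samples(d),
    missing_fraction = mean(is.na(as.matrix(d$values))),
    n_categorical = sum(d$feature_kinds == "categorical"),
    n_constant = n_const
  ), class = "autosig_meta")
}

#' @export
print.autosig_meta <- function(x, ...) {
  cat(sprintf("<autosig_meta> n=%d p=%d rarest=%d (%.1f%%) missing=%.1f%% categorical=%d constant=%d\n",
              x$n, x$p, x$rarest_class, 100 * x$imbalance_ratio,
              100 * x$missing_fraction, x$n_categorical, x$n_constant))
  invisible(x)
}

#' Stratified sample split
#'
#' Splits a dataset into two parts keeping each class's proportion within
#' one sample of the overall proportion. When group identifiers are present
#' whole groups are assigned to one side, never split.
#'
#' @param d an `autosig_dataset`
#' @param fraction fraction of samples in the first part, in (0,1)
#' @param seed integer seed; the same seed reproduces the same partition
#' @return list with elements `a` and `b`, both `autosig_dataset`s, plus
#'   `index_a`, `index_b` (row indices into `d`).
#' @export
stratified_split <- function(d, fraction, seed) {
  stopifnot(fraction > 0, fraction < 1)
  n <- n_samples(d)
  idx_a <- if (is.null(d$group_ids)) {
    with_seed(seed, {
      unlist(lapply(levels(d$outcome), function(lv) {
        rows <- which(d$outcome == lv)
        k <- round(fraction * length(rows))
        if (k < 1L || k >= length(rows))
          abort_autosig("degenerate_split",
                        sprintf("fraction %.3f leaves class '%s' empty on one side",
                                fraction, lv))
        sample(rows, k)
      }), use.names = FALSE)
    })
  } else {
    split_groups(d, fraction, seed)
  }
  idx_a <- sort(idx_a)
  idx_b <- setdiff(seq_len(n), idx_a)
  list(a = subset_dataset(d, idx_a), b = subset_dataset(d, idx_b),
       index_a = idx_a, index_b = idx_b)
}

# greedy group assignment: shuffle groups, fill part A per class until the
# per-class quota is reached; a group goes wholly to one side
split_groups <- function(d, fraction, seed) {
  groups <- split(seq_len(n_samples(d)), d$group_ids)
  quota <- round(fraction * as.integer(table(d$outcome)))
  names(quota) <- levels(d$outcome)
  with_seed(seed, {
    ord <- sample(length(groups))
    taken <- integer(0)
    filled <- setNames(numeric(length(quota)), names(quota))
    for (g in groups[ord]) {
      cls <- table(factor(d$outcome[g], levels = names(quota)))
      if (all(filled + cls <= quota + 1)) {  # within-one-sample tolerance
        taken <- c(taken, g)
        filled <- filled + cls
      }
    }
    if (any(filled < 1) || length(taken) >= n_samples(d))
      abort_autosig("degenerate_split", "group structure admits no valid stratified split")
    taken
  })
}

subset_dataset <- function(d, idx) {
  out <- d
  out$values <- d$values[idx, , drop = FALSE]
  rownames(out$values) <- NULL
  out$outcome <- d$outcome[idx]
  if (!is.null(d$group_ids)) out$group_ids <- d$group_ids[idx]
  out
}
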