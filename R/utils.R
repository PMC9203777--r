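# Internal helpers: structured errors, seeded evaluation, seed derivation.

#' @importFrom glmnet glmnet
#' @importFrom rpart rpart
#' @importFrom ranger ranger
#' @importFrom e1071 svm
#' @importFrom jsonlite write_json
#' @importFrom stats predict
NULL

abort_autosig <- function(class, message, ...) {
  cond <- structure(
    class = c(paste0("autosig_", class), "autosig_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, evaluates, and restores the caller's RNG state so that
#' seeded internals never perturb the user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds from a master seed; kept within 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483587L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
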