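# Internal helpers shared across modules.

#' @keywords internal
logit <- function(p) log(p / (1 - p))

#' @keywords internal
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so callers' RNG streams are untouched.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage seed from a top-level seed: stage k gets seed*100 + k,
# folded into the 32-bit integer range. Documented in the methods vignette.
#' @keywords internal
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 100 + k) %% 2147483647)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' @keywords internal
check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("invalid config field '%s': must be a scalar in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(TRUE)
}
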