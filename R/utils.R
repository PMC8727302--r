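# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates, restores. With `seed =
#' NULL` the expression runs under the ambient RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Derive a stage/sub-stream seed from a master seed. Stage seeds are spaced
# by a large odd constant so streams for different stages (and patients
# within the generator) never coincide; the result stays below 2^31 - 1.
derive_seed <- function(master, stage, index = 0L) {
  stages <- c(simulate = 1L, selection = 2L, preprocess = 3L, score = 4L,
              classify = 5L, de = 6L, bulkify = 7L, patient = 8L,
              contaminant = 9L)
  k <- stages[[stage]]
  (as.double(master) + 1000003 * k + 7919 * as.double(index)) %% 2147483629
}

# Signal an explicit "nothing survived the operation" condition rather than
# returning a silently empty object. Callers can catch class
# "relapsescore_empty".
stop_empty <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("relapsescore_empty", "error", "condition")))
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == floor(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
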