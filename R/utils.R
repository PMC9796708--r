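#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Spawn a deterministic sub-seed from a master seed
#'
#' Used by multi-stage procedures so each stage has its own reproducible
#' stream. Result stays below 2^31.
#'
#' @param seed master seed (integer).
#' @param offset stage offset (integer).
#' @return An integer seed.
#' @keywords internal
spawn_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + as.double(offset)) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_kin <- function(...) stop(..., call. = FALSE)
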