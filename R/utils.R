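#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so that seeded generators never disturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a master seed
#'
#' Deterministic mixing of a master seed with a stage name, kept below
#' 2^31 so the result is a valid R integer seed.
#'
#' @param master Integer master seed.
#' @param stage Character stage label.
#' @return Integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(master)) * 48271 + h * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
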