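#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one root seed.  Named
#' sub-streams (e.g. "cohort", "counts", "metabolome") get their own
#' derived seeds so stages can be regenerated independently without
#' consuming each other's random numbers.
#'
#' @param seed integer root seed.
#' @param stream character stream label.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483645 + 1)
}

#' Run an expression under a local RNG seed
#'
#' Restores the caller's RNG state afterwards, so library code does not
#' disturb user-level reproducibility.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# numeric matrix coercion with informative error
as_num_matrix <- function(x, what = "input") {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop(what, " must be numeric", call. = FALSE)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
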