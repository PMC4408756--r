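# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package operations do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_local_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive named substream seeds (< 2^31) from one master seed, so that the
# design, cohort and shuffle stages are independently reproducible.
substream_seeds <- function(seed, names) {
  with_local_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, length(names))
    stats::setNames(s, names)
  })
}

other_side <- function(side) {
  ifelse(side == "LEFT", "RIGHT", "LEFT")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stopifnot with a readable, single-sentence message
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
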