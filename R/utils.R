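#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage child seed from a global seed
#'
#' Hashes the stage name onto the global seed so that workflow stages can
#' be rerun in isolation while remaining jointly reproducible. The result
#' is always a valid 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
#' @examples
#' stage_seed(1, "simulate")
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L, nzchar(stage))
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage))) %% 99991L
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# internal: scalar checks used by constructors
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

geometric_mean <- function(x) exp(mean(log(x)))
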