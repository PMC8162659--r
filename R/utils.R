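#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` with the RNG seeded at `seed`, restoring the caller's RNG
#' state afterwards so simulation helpers do not perturb user scripts.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer")
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
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a labeled sub-seed from a top-level seed
#'
#' All randomness in the pipeline flows from one seed, fanned out to modules
#' through fixed offsets so stages stay independently reproducible.
#'
#' @param seed top-level integer seed.
#' @param offset small non-negative integer, one per pipeline stage.
#' @return An integer below 2^31.
#' @keywords internal
sub_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) %% 2e9 + 7L * offset) %% .Machine$integer.max)
}

# pooled (count-weighted) methylation level; the denominator is total depth
weighted_level <- function(count_meth, count_unmeth) {
  tot <- sum(as.numeric(count_meth)) + sum(as.numeric(count_unmeth))
  if (tot == 0) return(NA_real_)
  sum(as.numeric(count_meth)) / tot
}

`%||%` <- function(a, b) if (is.null(a)) b else a
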