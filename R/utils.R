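## Small shared helpers.

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from a global seed
#'
#' One global seed fans out to reproducible per-stage seeds via a counter
#' scheme, so individual stages can be rerun in isolation with the same
#' stream. Results stay within the 32-bit integer range.
#'
#' @param seed global integer seed
#' @param stage stage counter (small non-negative integer)
#' @return integer seed
#' @export
stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 131L + as.numeric(stage) * 7919) %%
             2147483647)
}
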