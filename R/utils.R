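#' Derive a child seed from a global seed and a counter
#'
#' One global seed fans out to per-subject and per-multistart child seeds via
#' a counter-based linear-congruential hash, so that adding subjects or
#' restarts never perturbs earlier streams.  All arithmetic stays below 2^53
#' and the result is a positive integer below 2^31.
#'
#' @param seed integer global seed.
#' @param counter nonnegative integer counter (subject index, restart index).
#' @return A positive integer seed.
#' @export
derive_seed <- function(seed, counter) {
  m <- 2147483647               # 2^31 - 1
  x <- (abs(as.double(seed)) %% m)
  x <- (x * 48271 + 1) %% m
  x <- (x + (as.double(counter) %% m) * 16807) %% m
  as.integer(x %% (m - 1)) + 1L
}

## evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
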