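#' Derive a named substream seed from a root seed
#'
#' All randomness in the package flows from one root seed through named
#' substreams, so that e.g. the background sample does not depend on how
#' many replicate splits were drawn before it. The derived seed is a
#' deterministic 31-bit hash of the root seed and the stream name.
#'
#' @param seed integer root seed.
#' @param stream character stream name (e.g. `"simulate"`, `"split"`).
#' @param index optional integer for per-replicate substreams.
#' @return a single integer in `[0, 2^31 - 1]`.
#' @export
substreamSeed <- function(seed, stream, index = 0L) {
  h <- as.double(seed %% 2147483647)
  for (b in c(utf8ToInt(stream), as.integer(index))) {
    h <- (h * 31 + as.double(b) + 1) %% 2147483647
  }
  as.integer(h)
}

# run expr under a local RNG state seeded from (seed, stream); global
# .Random.seed is untouched
withSubstream <- function(seed, stream, expr, index = 0L) {
  s <- substreamSeed(seed, stream, index)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(s)
  expr
}
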