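# Run code under a fixed RNG seed without disturbing the caller's stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a child seed deterministically
#'
#' Mixes a base seed with one or more stream indices (e.g. subject, pair,
#' variant) into a new seed in the 32-bit integer range, so that every
#' source of randomness in a pipeline can be governed by a single seed.
#'
#' @param seed Base integer seed.
#' @param ... Integer indices identifying the stream.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed)
  for (i in ix) s <- (s * 69069 + 12345 + i) %% 2147483629
  as.integer(s)
}

# run-length starts/lengths for a vector (like rle but keeps start indices)
runs_of <- function(x) {
  r <- rle(as.vector(x))
  ends <- cumsum(r$lengths)
  data.frame(value = r$values, start = ends - r$lengths + 1L,
             length = r$lengths, end = ends, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
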