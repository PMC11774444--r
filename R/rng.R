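# Seeded sub-stream management.  Every source of randomness in the package
# draws from a named sub-stream derived from one master seed, so enlarging a
# dataset (more words, more repetitions) never perturbs draws made by other
# sub-streams.

#' Derive a reproducible sub-stream seed
#'
#' Maps a master seed and a stream name to a deterministic integer seed in
#' `[0, 2^31 - 1)`.  Used internally so that token assignment, forward-model
#' weights, sensor noise and planted residuals each consume an independent,
#' stable random stream.
#'
#' @param seed Integer master seed.
#' @param name Character stream name, e.g. `"noise"`.
#' @return A single integer seed.
#' @examples
#' substream_seed(1L, "tokens")
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name),
            length(name) == 1L)
  m <- 2147483647  # 2^31 - 1, keeps derived seeds valid 32-bit integers
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% m
  as.integer((abs(seed) %% m * 48271 + h * 69621 + 7) %% m)
}

# Evaluate expr with the RNG seeded from (seed, name), restoring the caller's
# RNG state afterwards.
with_substream <- function(seed, name, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}
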