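# Seed substreams: every randomized stage draws its seed from the master
# seed and a stream name, so stages and subjects are reproducible
# independently of execution order.

#' Derive a named substream seed from a master seed
#'
#' Deterministic integer hash of (master seed, stream name) into
#' \[1, 2^31 - 2\], used to give each simulation block, bootstrap and
#' classifier stage its own reproducible stream.
#'
#' @param master integer master seed.
#' @param stream character stream name, e.g. `"sim/s01/nback.easy.b1"`.
#' @return a single integer seed.
#' @export
substream_seed <- function(master, stream) {
  m <- 2147483629                      # largest prime < 2^31
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(as.character(stream))) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
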