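# Reproducible seeding: a master seed spawns per-instance substreams by a
# counter scheme, so ensembles are reproducible and order-independent.

#' Derive a substream seed from a master seed and a counter
#'
#' Deterministic map `(seed, counter) -> seed` used throughout the package to
#' give every simulated instance (and every independent random stream inside
#' an instance) its own seed. The map is one step of the MINSTD linear
#' congruential generator offset by the counter,
#' `((seed mod m) * 48271 + counter) mod m` with `m = 2^31 - 1`, kept in
#' exact double arithmetic (products stay below 2^53) and never returning 0.
#'
#' @param seed integer master seed.
#' @param counter non-negative integer stream index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @examples
#' substream_seed(1, 1)
#' substream_seed(1, 2)
#' @export
substream_seed <- function(seed, counter) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  out <- (s * 48271 + as.numeric(counter)) %% m
  if (out == 0) out <- 1
  as.integer(out)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
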