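## Internal helpers: seeded evaluation and seed derivation.

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic integer hash chain used to give every stage, replicate and
#' outer-layer chromosome its own reproducible stream: mixing is a
#' multiply-add modulo the Mersenne prime 2^31 - 1, so derived seeds stay
#' within R's integer range and concurrent evaluation is reproducible.
#'
#' @param seed Integer master seed.
#' @param ... Further integers (stage index, generation, chromosome index).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (k in c(...)) {
    h <- (h * 48271 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

## Tiny FNV-1a string hash (hex) for run manifests.
hashString <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
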