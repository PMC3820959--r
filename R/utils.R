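# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps all package randomness explicit:
# every stochastic entry point takes a seed and nothing touches the global
# stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive independent sub-seeds from a master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.onLoad <- function(libname, pkgname) {
  # manifest partition contract: 126 = 45 acc + 69 gyro + 12 mixed
  invisible(feature_manifest())
}
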