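# Scoped RNG: run expr under a fixed seed without disturbing the caller's
# RNG stream. All randomness in the package flows through this.

withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of per-item integer seeds (< 2^31) from one master seed.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(2147483646L, n))
}
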