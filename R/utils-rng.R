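# RNG scoping helpers. All stochastic operations in the package run inside
# with_local_rng() so they are reproducible from their own seed argument and
# never disturb the caller's RNG state.

with_local_rng <- function(seed, code) {
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

# Deterministic per-subject stream seed, derived from the run seed and the
# subject's index so that results do not depend on cohort order. Kept below
# 2^31 - 1 (R integers are 32-bit).
subject_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647) * 48271 %% 2147483647 +
               index * 10007) %% 2147483647L
}
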