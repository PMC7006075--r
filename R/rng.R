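# Seed plumbing: every routine that needs randomness takes an integer seed
# and derives independent child seeds deterministically, so no function
# depends on (or clobbers) the caller's global RNG state.

# SplitMix64-style integer mix, reduced to the 31-bit range R accepts as a
# seed. `key` separates streams (e.g. per-tree, per-fold) drawn from the
# same parent seed.
derive_seed <- function(seed, key = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  x <- (as.double(seed) %% 2147483647) + 1
  k <- (as.double(key) %% 2147483647) + 1
  # two rounds of a multiplicative mix kept in double-safe range
  x <- (x * 48271) %% 2147483647
  x <- (x + k * 69621) %% 2147483647
  x <- (x * 16807) %% 2147483647
  as.integer(x %% 2147483646) + 1L
}

derive_seeds <- function(seed, n, key = 0L) {
  vapply(seq_len(n), function(i) derive_seed(seed, key * 1000003 + i),
         integer(1))
}

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
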