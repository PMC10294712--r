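# Internal helpers: deterministic RNG streams and seed derivation.
#
# All randomness in the package flows through `local_rng()` streams so that
# (a) the caller's .Random.seed is never disturbed and (b) every stage and
# every subsample has its own reproducible stream derived from one base seed
# by a fixed counter scheme. Derived seeds stay below 2^31 - 1.

# Deterministic seed derivation: base seed plus a stage offset and counter,
# folded into [1, 2^31 - 2]. The multiplier spreads consecutive counters.
derive_seed <- function(seed, stage = 0L, counter = 0L) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- (as.numeric(seed) %% m)
  s <- (s * 48271 + as.numeric(stage) * 1664525 +
          as.numeric(counter) * 22695477 + 1) %% m
  as.integer(s + (s == 0))
}

# A self-contained RNG stream: draws advance the stream, the global
# .Random.seed is saved and restored around every draw.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  with_state <- function(f) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    if (is.null(env$state)) {
      set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
               sample.kind = "Rejection")
    } else {
      assign(".Random.seed", env$state, globalenv())
    }
    out <- f()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
    out
  }
  list(
    runif = function(n, min = 0, max = 1)
      with_state(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1)
      with_state(function() stats::rnorm(n, mean, sd)),
    sample = function(x, size = length(x), replace = FALSE)
      with_state(function() sample(x, size, replace)),
    sample_int = function(n, size = n, replace = FALSE)
      with_state(function() sample.int(n, size, replace)),
    seeds = function(k)
      with_state(function() sample.int(2147483646L, k))
  )
}

# clip numeric vector into [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
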