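# Self-contained seeded RNG streams.  Every stochastic operation in the
# package draws from an explicit stream object so that results are
# reproducible from a single integer seed and independent of the global
# .Random.seed (which is saved and restored around every draw).

new_rng <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  e$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  e
}

rng_eval <- function(rng, fn) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  fn()
}

rng_sample <- function(rng, n, size = n, replace = FALSE)
  rng_eval(rng, function() sample.int(n, size, replace = replace))

rng_norm <- function(rng, n, mean = 0, sd = 1)
  rng_eval(rng, function() stats::rnorm(n, mean, sd))

rng_unif <- function(rng, n, min = 0, max = 1)
  rng_eval(rng, function() stats::runif(n, min, max))

# sub-seed derivation: deterministic, stays well below 2^31
# (double arithmetic is exact here: seed * 1000003 + i < 2^53)
rng_subseed <- function(seed, i)
  as.integer((as.numeric(seed) * 1000003 + i) %% 2147483629)
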