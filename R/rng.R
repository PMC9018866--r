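# Self-contained RNG streams.
#
# Every stochastic routine in the package draws from its own stream object so
# that simulations are reproducible from their stated seeds and never disturb
# (or depend on) the caller's global RNG state. A stream captures a private
# .Random.seed and swaps it in around each draw.

make_rng <- function(seed) {
  seed <- as.integer(seed) %% .Machine$integer.max
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed, kind = "Mersenne-Twister")
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())

  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    f()
  }

  list(
    runif = function(n = 1L) with_state(function() stats::runif(n)),
    rnorm = function(n = 1L, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd)),
    sample_int = function(n, size = 1L, replace = FALSE, prob = NULL)
      with_state(function() sample.int(n, size, replace = replace, prob = prob)),
    # derive a reproducible child seed (kept below 2^31)
    child_seed = function() with_state(function() sample.int(.Machine$integer.max - 1L, 1L))
  )
}

# deterministic child seed for named pipeline stages (kept below 2^31)
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147480000)
}
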