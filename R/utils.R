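# Seed-scoped RNG: every stochastic operation in the package draws from its
# own stream so results are reproducible under a caller-supplied seed and the
# caller's global RNG state is never disturbed.
local_rng <- function(seed) {
  state <- NULL
  run <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, globalenv())
    on.exit({
      state <<- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    expr_fun()
  }
  list(
    sample_int = function(n, size = n, replace = FALSE)
      run(function() sample.int(n, size, replace = replace)),
    runif = function(n, min = 0, max = 1)
      run(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1)
      run(function() stats::rnorm(n, mean, sd)),
    # derive a child seed (kept within 32-bit integer range)
    child_seed = function()
      run(function() sample.int(.Machine$integer.max, 1L))
  )
}

# clip numeric values into [lo, hi]
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)
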