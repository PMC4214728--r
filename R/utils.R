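# Seeded random draws that do not disturb the caller's RNG state. Each
# consumer owns one stream, advanced across calls, so results depend only on
# the seed and the order of draws within the stream.
local_rng <- function(seed) {
  state <- NULL
  with_state <- function(f, ...) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, globalenv())
    out <- f(...)
    state <<- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    out
  }
  list(
    rnorm = function(n, ...) with_state(stats::rnorm, n, ...),
    runif = function(n, ...) with_state(stats::runif, n, ...),
    rbinom = function(n, ...) with_state(stats::rbinom, n, ...)
  )
}

# deterministic 32-bit sub-seed for per-individual simulation streams
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 69069 + as.numeric(index) * 104729) %% 2147483647
}
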