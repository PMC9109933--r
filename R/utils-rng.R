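# RNG discipline: every stochastic operation accepts a seed and evaluates
# under a temporary RNG state, restoring the caller's stream afterwards.
# Sub-seeds for independent stages (effect draws, cohorts, coding sampling)
# are derived from one root seed so that changing one stage never perturbs
# another.

local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# k sub-seeds (kept below 2^31) derived from `seed`; when seed is NULL the
# ambient RNG stream is used, so unseeded calls remain stochastic.
derive_seeds <- function(seed, k) {
  local_seed(seed, sample.int(2147483646L, k))
}
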