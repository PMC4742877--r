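# Internal helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded generators do not perturb the global stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# population (n-divisor) standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# wrap an angle to (-pi, pi]
wrap_pi <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}
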