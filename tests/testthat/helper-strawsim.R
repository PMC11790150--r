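# Shared fixtures: small configurations built in code.

default_config <- function(seed = 1L, n_flowers = 10000L) {
  simulation_config(seed = seed, n_flowers = n_flowers)
}

small_config <- function(seed = 1L, n_flowers = 2000L) {
  simulation_config(seed = seed, n_flowers = n_flowers)
}

# tractable-support setting for the convolution oracle
tiny_visit <- function() visit_model(lambda_visits = 0.5, grains_per_visit = 2)

# exact mean/variance/skewness from a pmf over 0:(length-1)
pmf_moments <- function(pmf) {
  k <- seq_along(pmf) - 1
  m1 <- sum(k * pmf)
  m2 <- sum((k - m1)^2 * pmf)
  m3 <- sum((k - m1)^3 * pmf)
  list(mean = m1, var = m2, skew = m3 / m2^1.5)
}
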