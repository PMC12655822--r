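# Shared fixtures, built in code once per test run.

ref_lib <- simulate_reference_library()
ref_mat <- library_matrix(ref_lib)

# Analytic mean/sd of a truncated normal, the independent oracle for the
# rejection sampler.
truncnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  m <- mean + sd * (dnorm(a) - dnorm(b)) / Z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                 ((dnorm(a) - dnorm(b)) / Z)^2)
  list(mean = m, sd = sqrt(v))
}

# Random non-negative weight vectors for recovery properties.
random_weights <- function(n, seed) {
  withr::with_seed(seed, matrix(runif(n * 5, 0, 0.8), n, 5))
}

small_pipeline_config <- function() {
  pipeline_config(
    population = list(n_per_line = 30),
    classify = list(n_iterations = 3),
    predict = list(n_mixed = 30),
    embed = list(perplexities = c(5, 10), n_replicates = 2, max_iter = 200)
  )
}
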