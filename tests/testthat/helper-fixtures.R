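# Shared fixtures: draws from known Gaussian mixtures and a small simulated
# array reused across test files.

draw_mixture <- function(n, weights, means, sds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  rnorm(n, means[k], sds[k])
}

small_sim <- function(n_type1 = 1500, n_type2 = 4000, n_samples = 2,
                      seed = 11, ...) {
  simulate_array(simulation_spec(n_type1 = n_type1, n_type2 = n_type2,
                                 n_samples = n_samples, seed = seed, ...))
}

type2_values <- function(sim, sample = 2L) {
  sim$data[[sample + 1L]][sim$annotation$type == "II"]
}

type1_values <- function(sim, sample = 2L) {
  sim$data[[sample + 1L]][sim$annotation$type == "I"]
}
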