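# Shared fixtures: small synthetic neuron banks and sessions, built in code.

# trials x neurons rate matrix from per-neuron generative coefficients:
# r = b0 + bv*value + bs*side + bi*value*side + N(0, sigma)
make_neuron_bank <- function(n_trials, coefs, sigma = 1, seed = 1L) {
  set.seed(seed)
  value <- stats::runif(n_trials)
  side <- sample(c(-1, 1), n_trials, replace = TRUE)
  X <- cbind(1, value, side, value * side)
  mu <- X %*% t(coefs)  # coefs: neurons x 4 (b0, bv, bs, bi)
  list(rates = mu + matrix(stats::rnorm(length(mu), sd = sigma), nrow(mu)),
       value = value, side = side)
}

# quick small session for pipeline tests
small_session <- function(seed = 1L, ...) {
  generate_population_session(n_neurons = 30, n_trials = 400, seed = seed, ...)
}

# the end-to-end battery is expensive; compute it once per test run
.acc_cache <- new.env(parent = emptyenv())
acceptance_suite <- function() {
  if (is.null(.acc_cache$suite))
    .acc_cache$suite <- recovery_suite(sim_trials = 1e5, seed = 1)
  .acc_cache$suite
}
suite_row <- function(suite, check) suite[suite$check == check, , drop = FALSE]

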