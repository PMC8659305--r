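# Shared fixtures: built in code, deterministic given the seeds passed in.

full_questions <- function(seed = 42) {
  generate_questions(generator_config(), seed = seed)
}

full_design <- function() {
  build_design(generator_config())
}

# a parameter set whose expected sensitivity stays inside (0, 0.5) for the
# D and sigma ranges the generator produces (herding regime)
herding_params <- function() {
  # slopes small enough that <S> stays inside (0, 0.5) even at the extreme
  # distances the truncated Laplace tails can produce (|D| up to ~10)
  influence_params(
    tau1 = list(m_g = 0.5, sigma_g = 0.2, D0 = -0.2, alpha = 0.3,
                beta_minus = 0.003, beta_plus = 0.006),
    tau_gt1 = list(D0 = -0.2, alpha = 0.3, beta_minus = 0.003,
                   beta_plus = 0.006, beta_prime = -0.05,
                   m_g_intercept = 0.55, m_g_slope = -0.05,
                   sigma_g_intercept = 0.2, sigma_g_slope = 0.05)
  )
}

# small simulation reused by several accuracy tests
small_sim <- function(n_runs = 10, seed = 7, params = default_influence_params()) {
  simulate_experiment(full_questions(), full_design(), params,
                      n_runs = n_runs, seed = seed)
}
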