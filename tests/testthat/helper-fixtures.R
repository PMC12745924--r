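# Shared fixtures built in code; all randomness under fixed seeds.

# small noise-free environment for deterministic checks
env_flat <- function(n = 48) {
  simulate_environment(n, seasonal_amp = 0, trend = 0, noise_sd = 0, seed = 1)
}

# quiet wrapper: several fitters warn legitimately on degenerate fixtures
quiet <- function(expr) suppressWarnings(expr)

# capture table from a tiny deterministic population (no deaths, no noise,
# perfect detection): SVL sequences follow the growth curve exactly
perfect_population <- function(n = 40, months = 30, seed = 2) {
  tp <- truth_params(gompertz_b0 = -30, gompertz_b1 = 0,
                     beta_phi = c(0, 0, 0, 0), beta_p = c(30, 0, 0, 0),
                     svl_obs_sd = 0, seed = seed)
  env <- simulate_environment(months, seed = seed)
  sim <- simulate_population(tp, n, months, env, unknown_sex_frac = 0,
                             seed = seed)
  list(tp = tp, env = env, sim = sim)
}

# fits list built from ground truth for kernel-level tests
truth_fit_set <- function(n_env = 60, ...) {
  tp <- truth_params(...)
  env <- simulate_environment(n_env, noise_sd = 0, seed = 1)
  env$mean_svl <- 60
  list(tp = tp, env = env, fits = truth_fits(tp, env))
}
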