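# Shared fixtures. Expensive fits are cached so that several test
# blocks can interrogate the same posterior without re-running MCMC.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_spec <- function(n) cohort_spec(n, scaled_strata(n))

# full-size pooled fits at the published generating values (seed 1,
# desk-scale iteration budget)
pooled_fit <- function(preset) {
  cached(paste0("pooled_", preset), {
    sim <- simulate_cohort(preset, seed = 1)
    fit <- fit_cpt(sim$observations, sim$tasks[[1]],
                   mcmc_config(20000, 2000, seed = 1))
    list(sim = sim, fit = fit)
  })
}

# a small homogeneous cohort with explicit (alpha, beta) and noise
small_sim <- function(alpha, beta, sigma_eps, n = 20, seed = 1,
                      preset_tasks = "task1") {
  cfg <- generative_config(gamma = c(alpha, rep(0, 6)),
                           xi = c(beta, rep(0, 6)),
                           lam = 1.091, sigma_eps = sigma_eps,
                           sigma_eta = 0, sigma_zeta = 0)
  simulate_cohort(seed = seed, spec = small_spec(n), config = cfg,
                  tasks = default_tasks()[preset_tasks])
}
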