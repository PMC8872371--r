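test_that("log posterior decomposes into prior plus per-row densities", {
  task <- default_tasks()$task1
  pp <- cpt_params(lam = 1.2, alpha = 1.1, beta = 0.6, sigma_eps = 0.02)
  pri <- default_priors()

  # no observations: the prior alone
  empty <- data.frame(respondent_id = character(), task_id = integer(),
                      scenario_id = character(), probability = numeric(),
                      loss_usd = numeric(), ce_usd = numeric())
  lp0 <- log_posterior(pp, empty, task)
  prior_oracle <- dlnorm(1.2, 0, 0.5, log = TRUE) +
    dlnorm(1.1, 0, 0.5, log = TRUE) - log(2 - 0.3) +
    (0.5 * log(2 / pi) - log(0.5) - 0.02^2 / (2 * 0.25))
  expect_equal(lp0, prior_oracle, tolerance = 1e-12)

  # five-row fixture against a term-by-term summation
  sc <- task_scenarios(task)[c(1, 7, 13, 19, 25), ]
  obs <- data.frame(respondent_id = "r1", task_id = 1L,
                    scenario_id = sc$scenario_id,
                    probability = sc$probability, loss_usd = sc$loss_usd,
                    ce_usd = sc$loss_usd * c(0.1, 0.2, 0.15, 0.4, 0.8),
                    stringsAsFactors = FALSE)
  terms <- vapply(seq_len(5), function(i) {
    cn <- obs$ce_usd[i] / 1e5; xn <- obs$loss_usd[i] / 1e5
    v_ce <- -pp$lam * cn^pp$alpha
    mu <- cpt_weight(obs$probability[i], pp) * (-pp$lam * xn^pp$alpha)
    dnorm(v_ce, mu, pp$sigma_eps, log = TRUE)
  }, numeric(1))
  expect_equal(log_posterior(pp, obs, task), prior_oracle + sum(terms),
               tolerance = 1e-10)

  # an observation exactly at the prediction contributes the mode density
  one <- obs[1, ]
  one$ce_usd <- ce_predict(one$probability, one$loss_usd, task, pp)
  expect_equal(log_posterior(pp, one, task) - lp0,
               dnorm(0, 0, pp$sigma_eps, log = TRUE), tolerance = 1e-8)

  # impossible state is -Inf, not an exception
  pp0 <- cpt_params(lam = 1.2, alpha = 1.1, beta = 0.6, sigma_eps = 0)
  expect_identical(log_posterior(pp0, obs, task), -Inf)
})

test_that("batch-means MC error behaves like a standard error", {
  expect_equal(mc_error(rep(2.5, 400)), 0)
  expect_error(mc_error(rnorm(50)), class = "cpt_chain_error")

  set.seed(101)
  iid <- rnorm(10000)
  # analytic SE of the mean for iid draws is 1/sqrt(n) = 0.01
  expect_lt(abs(mc_error(iid) - 0.01), 0.003)

  # strong positive autocorrelation inflates the error
  rho <- 0.9
  innov <- rnorm(10000, sd = sqrt(1 - rho^2))
  ar1 <- as.numeric(stats::filter(innov, rho, method = "recursive"))
  expect_gt(mc_error(ar1), 2 * mc_error(iid))
})

test_that("posterior summaries use interpolated empirical quantiles", {
  const <- summarize_chain(rep(3.2, 500), start = 1, name = "c")
  expect_equal(const$mean, 3.2)
  expect_equal(const$sd, 0)
  expect_equal(const$median, 3.2)
  expect_equal(const$q2_5, 3.2)
  expect_equal(const$q97_5, 3.2)

  s <- summarize_chain(as.numeric(1:100), start = 7, name = "seq")
  expect_equal(s$median, 50.5)   # order-statistics midpoint
  expect_equal(s$start, 7L)
  expect_equal(s$sample, 100L)

  set.seed(5)
  for (i in 1:5) {
    s <- summarize_chain(rcauchy(300))
    expect_true(s$q2_5 <= s$median && s$median <= s$q97_5)
  }
  expect_error(summarize_chain(numeric()), class = "cpt_chain_error")
})

test_that("degenerate designs are rejected with a named error", {
  task <- default_tasks()$task1
  sc <- task_scenarios(task)[1, ]
  single <- data.frame(respondent_id = sprintf("r%d", 1:30), task_id = 1L,
                       scenario_id = sc$scenario_id,
                       probability = sc$probability, loss_usd = sc$loss_usd,
                       ce_usd = 0.2 * sc$loss_usd, stringsAsFactors = FALSE)
  expect_error(fit_cpt(single, task, mcmc_config(1000, 100)),
               class = "cpt_design_error")
  sim <- small_sim(1.2, 0.6, 0.01, n = 20)
  expect_error(fit_cpt(sim$observations[1:10, ], sim$tasks[[1]],
                       mcmc_config(1000, 100)),
               class = "cpt_design_error")
})

test_that("noiseless fits agree with the grid-search and NLS oracles", {
  sim <- small_sim(alpha = 1.2, beta = 0.5, sigma_eps = 0, n = 8)
  task <- sim$tasks[[1]]
  fit <- fit_cpt(sim$observations, task, mcmc_config(4000, 1000, seed = 2))
  expect_equal(fit$summary$median[fit$summary$parameter == "alpha"], 1.2,
               tolerance = 0.02)
  expect_equal(fit$summary$median[fit$summary$parameter == "beta"], 0.5,
               tolerance = 0.02)
  gs <- grid_search_cpt(sim$observations, task,
                        alpha_grid = seq(1.0, 1.4, by = 0.01),
                        beta_grid = seq(0.4, 0.6, by = 0.01))
  expect_equal(gs$alpha, 1.2, tolerance = 0.011)
  expect_equal(gs$beta, 0.5, tolerance = 0.011)
  ls <- fit_cpt_ls(sim$observations, task)
  expect_equal(ls$alpha, 1.2, tolerance = 1e-4)
  expect_equal(ls$beta, 0.5, tolerance = 1e-4)
})

test_that("posterior mode matches the least-squares route on several fixtures", {
  cases <- list(c(0.8, 0.45), c(1.433, 0.525), c(1.176, 0.382),
                c(1.8, 0.9), c(1.0, 1.3))
  for (i in seq_along(cases)) {
    a <- cases[[i]][1]; b <- cases[[i]][2]
    sim <- small_sim(alpha = a, beta = b, sigma_eps = 0, n = 8,
                     seed = 100 + i)
    fit <- suppressWarnings(
      fit_cpt(sim$observations, sim$tasks[[1]],
              mcmc_config(3000, 800, seed = i)))
    ls <- fit_cpt_ls(sim$observations, sim$tasks[[1]])
    expect_equal(fit$summary$median[fit$summary$parameter == "alpha"],
                 ls$alpha, tolerance = 0.02)
    expect_equal(fit$summary$median[fit$summary$parameter == "beta"],
                 ls$beta, tolerance = 0.02)
  }
})

test_that("chains are reproducible given the seed", {
  sim <- small_sim(1.3, 0.7, 0.02, n = 6)
  cfg <- mcmc_config(2000, 500, seed = 77)
  f1 <- suppressWarnings(fit_cpt(sim$observations, sim$tasks[[1]], cfg))
  f2 <- suppressWarnings(fit_cpt(sim$observations, sim$tasks[[1]], cfg))
  expect_identical(f1$chains, f2$chains)
})

test_that("degenerate response patterns surface in the diagnostics", {
  # data generated exactly at the lower support edge of beta: the
  # posterior piles against the edge and the boundary warning fires
  cfg <- generative_config(gamma = c(1.2, rep(0, 6)),
                           xi = c(0.3, rep(0, 6)),
                           lam = 1.091, sigma_eps = 0.005,
                           sigma_eta = 0, sigma_zeta = 0)
  sim <- simulate_cohort(seed = 5, spec = small_spec(8), config = cfg,
                         tasks = default_tasks()["task1"])
  expect_warning(
    fit <- fit_cpt(sim$observations, sim$tasks[[1]],
                   mcmc_config(3000, 800, seed = 3)),
    class = "cpt_boundary_warning")
  expect_true(fit$diagnostics$beta_boundary)
  expect_gt(mean(fit$chains[, "beta"] < 0.3 + 0.034), 0.5)

  # paying the full loss in every scenario cannot be explained by any
  # weighting curve; the fit absorbs the misfit into the noise scale,
  # which blows up relative to the value scale
  task <- default_tasks()$task1
  sc <- task_scenarios(task)
  obs <- data.frame(respondent_id = "r1", task_id = 1L,
                    scenario_id = sc$scenario_id,
                    probability = sc$probability, loss_usd = sc$loss_usd,
                    ce_usd = sc$loss_usd, stringsAsFactors = FALSE)
  f2 <- suppressWarnings(fit_cpt(obs, task, mcmc_config(3000, 800, seed = 3)))
  tau <- mean(f2$chains[, "sigma_eps"] / f2$chains[, "lam"])
  expect_gt(tau, 0.1)   # orders of magnitude above elicitation noise
})

test_that("the loss scale stays prior-dominated (weakly identified)", {
  # lambda cancels from the CE identity, so the data cannot move it:
  # two different datasets must return the same broad posterior
  f1 <- suppressWarnings(fit_cpt(small_sim(1.4, 0.5, 0.01, n = 10,
                                           seed = 21)$observations,
                                 default_tasks()$task1,
                                 mcmc_config(6000, 1500, seed = 1)))
  f2 <- suppressWarnings(fit_cpt(small_sim(0.9, 1.1, 0.01, n = 25,
                                           seed = 22)$observations,
                                 default_tasks()$task1,
                                 mcmc_config(6000, 1500, seed = 2)))
  lam1 <- f1$summary[f1$summary$parameter == "lam", ]
  lam2 <- f2$summary[f2$summary$parameter == "lam", ]
  a1 <- f1$summary[f1$summary$parameter == "alpha", ]
  expect_gt(lam1$sd, 0.3)              # stays broad: no collapse with data
  expect_gt(lam2$sd, 0.3)
  expect_lt(abs(lam1$mean - lam2$mean), 0.25)
  expect_lt(a1$sd, 0.05)               # while alpha is sharply identified
})
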