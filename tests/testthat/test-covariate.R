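make_null_sim <- function(n = 30, seed = 1) {
  simulate_cohort("null", seed = seed, spec = small_spec(n))
}

test_that("two-stage fit recovers degenerate covariate structures", {
  prof <- generate_profiles(small_spec(20), seed = 4)

  # constant parameters, no noise: zero slopes, intercepts at the truth
  cfg <- generative_config(gamma = c(1.2, rep(0, 6)), xi = c(0.6, rep(0, 6)),
                           sigma_eps = 0, sigma_eta = 0, sigma_zeta = 0)
  par <- generate_params(prof, cfg, seed = 4)
  obs <- generate_ce(prof, par, default_tasks(), cfg, seed = 4)
  ts <- suppressWarnings(two_stage_fit(obs, prof, default_tasks()))
  expect_equal(unname(ts$gamma["intercept", "estimate"]), 1.2,
               tolerance = 1e-3)
  expect_equal(unname(ts$xi["intercept", "estimate"]), 0.6,
               tolerance = 1e-3)
  expect_true(all(abs(ts$gamma[-1, "estimate"]) < 1e-4))
  expect_true(all(abs(ts$xi[-1, "estimate"]) < 1e-4))

  # alpha linear in the scale code only: exact recovery of the slope
  cfg2 <- generative_config(gamma = c(0.9, 0, 0, 0, 0, 0.1, 0),
                            xi = c(0.6, rep(0, 6)),
                            sigma_eps = 0, sigma_eta = 0, sigma_zeta = 0)
  par2 <- generate_params(prof, cfg2, seed = 4)
  obs2 <- generate_ce(prof, par2, default_tasks(), cfg2, seed = 4)
  ts2 <- suppressWarnings(two_stage_fit(obs2, prof, default_tasks()))
  expect_equal(unname(ts2$gamma["scale", "estimate"]), 0.1,
               tolerance = 1e-3)
  expect_equal(unname(ts2$gamma["intercept", "estimate"]), 0.9,
               tolerance = 1e-3)
})

test_that("shuffling profiles against respondents destroys the slopes", {
  sim <- simulate_cohort("table3", seed = 6, spec = small_spec(40))
  ts <- suppressWarnings(two_stage_fit(sim$observations, sim$profiles,
                                       sim$tasks))
  est <- ts$per_respondent[ts$per_respondent$converged, ]
  prof <- sim$profiles[match(est$respondent_id, sim$profiles$respondent_id), ]
  # permutation-null oracle: regress stage-1 estimates on shuffled codes
  set.seed(99)
  n_sig <- 0; n_tot <- 0
  for (perm in 1:20) {
    shuffled <- prof[sample(nrow(prof)), c("gender", "job_title", "funding",
                                           "ltcf_type", "scale", "strategy")]
    for (resp in list(est$alpha, est$beta)) {
      pv <- summary(lm(resp ~ ., data = shuffled))$coefficients[-1, 4]
      n_sig <- n_sig + sum(pv < 0.1)
      n_tot <- n_tot + length(pv)
    }
  }
  expect_lt(n_sig / n_tot, 0.2)  # nominal 10% under the null
})

test_that("binary recoding shifts intercepts but not slopes", {
  sim <- simulate_cohort("table3", seed = 8, spec = small_spec(24))
  ts1 <- suppressWarnings(two_stage_fit(sim$observations, sim$profiles,
                                        sim$tasks))
  recoded <- sim$profiles
  recoded$gender <- recoded$gender - 1L   # (1,2) -> (0,1)
  ts2 <- suppressWarnings(two_stage_fit(sim$observations, recoded,
                                        sim$tasks))
  expect_equal(ts1$gamma["gender", "estimate"],
               ts2$gamma["gender", "estimate"], tolerance = 1e-8)
  expect_equal(ts1$xi["gender", "estimate"], ts2$xi["gender", "estimate"],
               tolerance = 1e-8)
  expect_equal(unname(ts2$gamma["intercept", "estimate"]),
               unname(ts1$gamma["intercept", "estimate"] +
                        ts1$gamma["gender", "estimate"]),
               tolerance = 1e-8)
})

test_that("hierarchical fit leaves null slopes unflagged", {
  sim <- make_null_sim(n = 40, seed = 2)
  hf <- suppressWarnings(
    fit_hierarchical(sim$observations, sim$profiles, sim$tasks,
                     hier_config(6000, 2500, seed = 2)))
  slopes <- hf$report[hf$report$term != "intercept", ]
  # each 90% interval misses zero with 10% probability under the null;
  # allow the binomial 3-sigma upper bound on 12 draws
  expect_lte(sum(slopes$flag != ""), 4)
  expect_equal(nrow(slopes), 12)
  # intercepts sit near the generating values
  ints <- hf$report[hf$report$term == "intercept", ]
  expect_equal(ints$estimate[ints$equation == "alpha"], 1.0,
               tolerance = 0.15)
  expect_equal(ints$estimate[ints$equation == "beta"], 0.7,
               tolerance = 0.15)
})

test_that("hierarchical and two-stage routes agree on a gender fixture", {
  # gender drives the weighting curvature; other factors vary minimally
  n <- 24
  # each remaining factor varies through a different single respondent
  # so the design matrix keeps full rank
  off_one <- function(k) { v <- rep(1L, n); v[k] <- 2L; v }
  prof <- data.frame(respondent_id = sprintf("r%03d", 1:n),
                     gender = rep(1:2, n / 2),
                     job_title = off_one(1), funding = off_one(3),
                     ltcf_type = off_one(5), scale = off_one(7),
                     strategy = off_one(9),
                     stringsAsFactors = FALSE)
  cfg <- generative_config(gamma = c(1.1, rep(0, 6)),
                           xi = c(0.5, 0.09, rep(0, 5)),
                           sigma_eps = 0.01, sigma_eta = 0.02,
                           sigma_zeta = 0.02)
  par <- generate_params(prof, cfg, seed = 12)
  obs <- generate_ce(prof, par, default_tasks(), cfg, seed = 12)
  hf <- suppressWarnings(
    fit_hierarchical(obs, prof, default_tasks(),
                     hier_config(6000, 2500, seed = 12)))
  ts <- suppressWarnings(two_stage_fit(obs, prof, default_tasks()))
  hier_est <- hf$report$estimate[hf$report$equation == "beta" &
                                   hf$report$term == "gender"]
  ts_est <- unname(ts$xi["gender", "estimate"])
  ts_se <- unname(ts$xi["gender", "se"])
  hier_halfwidth <- diff(unlist(
    hf$report[hf$report$equation == "beta" & hf$report$term == "gender",
              c("lower", "upper")])) / 2
  margin <- max(hier_halfwidth, qnorm(0.95) * ts_se)
  expect_lt(abs(hier_est - ts_est), margin)
  expect_lt(abs(hier_est - 0.09), 0.05)
})

test_that("covariate fits reject broken inputs by name", {
  sim <- simulate_cohort("table3", seed = 3, spec = small_spec(24))
  expect_error(
    fit_hierarchical(sim$observations, sim$profiles[-1, ], sim$tasks),
    class = "cpt_profile_error")
  const_prof <- sim$profiles
  const_prof$funding <- 1L
  expect_error(
    fit_hierarchical(sim$observations, const_prof, sim$tasks),
    class = "cpt_inestimable_error")
  few <- simulate_cohort("table3", seed = 3, spec = small_spec(12))
  expect_error(
    fit_hierarchical(few$observations, few$profiles, few$tasks),
    class = "cpt_design_error")
  expect_error(
    two_stage_fit(sim$observations[sim$observations$scenario_id == "1.1", ],
                  sim$profiles, sim$tasks),
    class = "cpt_design_error")
})

test_that("significance flags nest and respect the interval rules", {
  # synthetic coefficient chains with unambiguous placements
  set.seed(33)
  n <- 4000
  chains <- cbind(
    matrix(rnorm(n * 14, mean = 0, sd = 1), n, 14),
    rnorm(n, 0.1, 0.01), rnorm(n, 0.05, 0.01),
    rnorm(n, 1.1, 0.3), rnorm(n, 0.01, 0.003))
  colnames(chains) <- c(paste0("gamma_", cptrisk:::coef_terms),
                        paste0("xi_", cptrisk:::coef_terms),
                        "sigma_eta", "sigma_zeta", "lam", "sigma_eps")
  chains[, "gamma_gender"] <- rnorm(n, 5, 0.1)       # decisively nonzero
  chains[, "gamma_funding"] <- rnorm(n, 0.2, 0.1)    # borderline (90% only)
  chains[, "xi_scale"] <- rnorm(n, 0, 0.1)           # null
  fake <- structure(list(coef_chains = chains), class = "cpt_hier_fit")
  rep <- flag_significance(fake)
  get_flag <- function(eq, term)
    rep$flag[rep$equation == eq & rep$term == term]
  expect_equal(get_flag("alpha", "gender"), "**")
  expect_equal(get_flag("alpha", "funding"), "*")
  expect_equal(get_flag("beta", "scale"), "")
  # nesting: every "**" coefficient also has 90% evidence
  starred <- rep[rep$flag == "**", ]
  expect_true(all(starred$lower * starred$upper > 0))
  # intercepts are never flagged
  expect_true(all(rep$flag[rep$term == "intercept"] == ""))
})
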