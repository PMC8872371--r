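# Linking per-respondent CPT parameters to the six coded
# sociodemographic factors:
#   alpha_i = gamma0 + sum_m gamma_m theta_im + eta_i
#   beta_i  = xi0    + sum_m xi_m    theta_im + zeta_i
# Primary route: joint hierarchical MCMC over all respondent-level
# parameters, the coefficient vectors, residual SDs, global loss scale
# and observation noise. Cross-check route: per-respondent nonlinear
# least squares followed by ordinary least squares on the codes.

#' Configuration for the hierarchical covariate fit
#'
#' @param n_iter,n_burn,thin,seed MCMC budget and seed (desk-scale
#'   defaults; adaptation is frozen at burn-in end).
#' @param priors priors for the global loss scale and observation
#'   noise, see \code{\link{default_priors}}. Coefficients get flat
#'   priors; residual variances get a vague inverse-gamma
#'   (`a0`, `b0`).
#' @param beta_support,alpha_min supports for the per-respondent
#'   curvatures (shared with the pooled fit).
#' @param task_offset if `TRUE`, adds additive task-2 offsets to both
#'   curvatures so the two decision tasks may differ systematically;
#'   the default pools tasks without offsets.
#' @param a0,b0 inverse-gamma hyperparameters for the residual
#'   variances.
#' @return An object of class \code{"hier_config"}.
#' @export
hier_config <- function(n_iter = 12000L, n_burn = 4000L, thin = 1L,
                        seed = 1L, priors = default_priors(),
                        beta_support = c(0.3, 2), alpha_min = 0.05,
                        task_offset = FALSE, a0 = 0.01, b0 = 0.01) {
  n_iter <- as.integer(n_iter); n_burn <- as.integer(n_burn)
  if (n_burn >= n_iter)
    cpt_abort("`n_burn` must be smaller than `n_iter`", "cpt_config_error")
  check_beta_support(beta_support)
  structure(list(n_iter = n_iter, n_burn = n_burn, thin = as.integer(thin),
                 seed = as.integer(seed), priors = priors,
                 beta_support = beta_support, alpha_min = alpha_min,
                 task_offset = isTRUE(task_offset), a0 = a0, b0 = b0),
            class = "hier_config")
}

coef_terms <- c("intercept", "gender", "job_title", "funding",
                "ltcf_type", "scale", "strategy")

# long-format design shared by both covariate routes
hier_data <- function(observations, profiles, tasks) {
  tasks <- task_registry(tasks)
  rid <- unique(observations$respondent_id)
  missing_prof <- setdiff(rid, profiles$respondent_id)
  if (length(missing_prof))
    cpt_abort(sprintf("respondent(s) without profile: %s",
                      paste(utils::head(missing_prof, 5), collapse = ", ")),
              "cpt_profile_error")
  profiles <- profiles[match(rid, profiles$respondent_id), , drop = FALSE]
  for (f in factor_names)
    if (length(unique(profiles[[f]])) < 2L)
      cpt_abort(sprintf(
        "factor `%s` takes a single value cohort-wide and is inestimable", f),
        "cpt_inestimable_error")
  o <- observations[order(match(observations$respondent_id, rid)), ,
                    drop = FALSE]
  scale_of <- vapply(tasks, function(t) t$money_scale, numeric(1))
  sc <- scale_of[as.character(o$task_id)]
  if (any(is.na(sc)))
    cpt_abort("observations refer to a task not in `tasks`",
              "cpt_unknown_task")
  list(
    resp = match(o$respondent_id, rid),
    rid = rid,
    nr = length(rid),
    logc = log(o$ce_usd / sc),
    logx = log(o$loss_usd / sc),
    p = o$probability,
    t2 = o$task_id != min(o$task_id),
    theta = cbind(intercept = 1,
                  as.matrix(profiles[, factor_names])),
    n = nrow(o)
  )
}

#' Joint hierarchical Bayesian fit of the covariate model
#'
#' Samples, by Metropolis within Gibbs, the per-respondent curvatures
#' \eqn{(\alpha_i, \beta_i)} (random-walk updates vectorized across
#' respondents), the coefficient vectors \eqn{\gamma, \xi} and residual
#' SDs \eqn{\sigma_\eta, \sigma_\zeta} (conjugate Gibbs draws), and the
#' global loss scale and observation noise (the same
#' ridge parameterization as \code{\link{fit_cpt}}). Respondent
#' curvatures are constrained to their supports; respondents whose
#' posterior sits against a support edge are flagged in the output.
#'
#' @param observations a validated observations data frame (may pool
#'   both tasks).
#' @param profiles respondent profile data frame with the six coded
#'   factors.
#' @param tasks list of \code{\link{decision_task}} objects referenced
#'   by the observations.
#' @param config a \code{\link{hier_config}}.
#' @return An object of class \code{"cpt_hier_fit"}: `coef_chains`
#'   (matrix of coefficient draws), `summary`, `report` (coefficient
#'   table with significance flags), `respondent` (posterior means and
#'   boundary flags for \eqn{\alpha_i, \beta_i}), `diagnostics`,
#'   `accept`, `config`.
#' @export
fit_hierarchical <- function(observations, profiles, tasks,
                             config = hier_config()) {
  stopifnot(inherits(config, "hier_config"))
  d <- hier_data(observations, profiles, tasks)
  if (d$nr < 20L)
    cpt_abort("need at least 20 respondents", "cpt_design_error")
  supp <- config$beta_support
  amin <- config$alpha_min
  priors <- config$priors
  set.seed(config$seed)

  # initialization from the two-stage route (point estimates only)
  init <- two_stage_init(d, supp, amin)
  alpha <- init$alpha; beta <- init$beta
  gam <- init$gamma; xi <- init$xi
  sig_eta <- max(init$sigma_eta, 1e-3)
  sig_zeta <- max(init$sigma_zeta, 1e-3)
  tau <- max(init$tau, 1e-6)
  lam <- 1
  d_a <- 0; d_b <- 0  # task-2 offsets (active only with task_offset)

  XtX <- crossprod(d$theta)
  Rchol <- chol(XtX)
  nr <- d$nr
  np <- ncol(d$theta)

  a_obs <- function(alpha) alpha[d$resp] + if (config$task_offset) d_a * d$t2 else 0
  b_obs <- function(beta) beta[d$resp] + if (config$task_offset) d_b * d$t2 else 0

  calpha <- exp(a_obs(alpha) * d$logc)
  xalpha <- exp(a_obs(alpha) * d$logx)
  w <- weight_fn(d$p, b_obs(beta))
  r <- calpha - w * xalpha
  ss_i <- drop(rowsum(r * r, d$resp))
  n_i <- drop(rowsum(rep(1, d$n), d$resp))

  lsc <- c(alpha = log(0.02), beta = log(0.02), tau = -2, lam = -1.5,
           off = log(0.01))
  n_keep <- (config$n_iter - config$n_burn) %/% config$thin
  cn <- c(paste0("gamma_", coef_terms), paste0("xi_", coef_terms),
          "sigma_eta", "sigma_zeta", "lam", "sigma_eps",
          if (config$task_offset) c("delta_alpha", "delta_beta"))
  coef_chains <- matrix(NA_real_, n_keep, length(cn),
                        dimnames = list(NULL, cn))
  asum <- numeric(nr); bsum <- numeric(nr)
  a_edge <- numeric(nr); b_edge <- numeric(nr)
  acc <- c(alpha = 0, beta = 0)
  kept <- 0L

  for (it in seq_len(config$n_iter)) {
    adapting <- it <= config$n_burn
    g_ad <- if (adapting) min(0.25, 2 / sqrt(it)) else 0
    mu_a <- drop(d$theta %*% gam)
    mu_b <- drop(d$theta %*% xi)

    # per-respondent alpha (vectorized independent RW)
    a_p <- alpha + stats::rnorm(nr, 0, exp(lsc["alpha"]))
    ok <- a_p > amin
    calpha_p <- exp(a_obs(a_p) * d$logc)
    xalpha_p <- exp(a_obs(a_p) * d$logx)
    r_p <- calpha_p - w * xalpha_p
    ss_p <- drop(rowsum(r_p * r_p, d$resp))
    logacc <- (ss_i - ss_p) / (2 * tau^2) +
      stats::dnorm(a_p, mu_a, sig_eta, log = TRUE) -
      stats::dnorm(alpha, mu_a, sig_eta, log = TRUE)
    logacc[!ok] <- -Inf
    take <- log(stats::runif(nr)) < logacc
    if (any(take)) {
      alpha[take] <- a_p[take]
      obs_take <- take[d$resp]
      calpha[obs_take] <- calpha_p[obs_take]
      xalpha[obs_take] <- xalpha_p[obs_take]
      ss_i[take] <- ss_p[take]
    }
    if (adapting)
      lsc["alpha"] <- lsc["alpha"] + g_ad * (mean(pmin(1, exp(logacc))) - 0.35)
    else acc["alpha"] <- acc["alpha"] + mean(take)

    # per-respondent beta
    b_p <- beta + stats::rnorm(nr, 0, exp(lsc["beta"]))
    ok <- b_p >= supp[1] & b_p <= supp[2]
    bo <- b_obs(b_p)
    w_p <- weight_fn(d$p, pmin(pmax(bo, 1e-3), 50))
    r_p <- calpha - w_p * xalpha
    ss_p <- drop(rowsum(r_p * r_p, d$resp))
    logacc <- (ss_i - ss_p) / (2 * tau^2) +
      stats::dnorm(b_p, mu_b, sig_zeta, log = TRUE) -
      stats::dnorm(beta, mu_b, sig_zeta, log = TRUE)
    logacc[!ok] <- -Inf
    take <- log(stats::runif(nr)) < logacc
    if (any(take)) {
      beta[take] <- b_p[take]
      obs_take <- take[d$resp]
      w[obs_take] <- w_p[obs_take]
      ss_i[take] <- ss_p[take]
    }
    if (adapting)
      lsc["beta"] <- lsc["beta"] + g_ad * (mean(pmin(1, exp(logacc))) - 0.35)
    else acc["beta"] <- acc["beta"] + mean(take)

    # coefficients and residual SDs (conjugate, flat prior on coefs)
    ghat <- solve(XtX, crossprod(d$theta, alpha))
    gam <- drop(ghat + sig_eta * backsolve(Rchol, stats::rnorm(np)))
    ss_a <- sum((alpha - drop(d$theta %*% gam))^2)
    sig_eta <- sqrt(1 / stats::rgamma(1, config$a0 + nr / 2,
                                      config$b0 + ss_a / 2))
    xhat <- solve(XtX, crossprod(d$theta, beta))
    xi <- drop(xhat + sig_zeta * backsolve(Rchol, stats::rnorm(np)))
    ss_b <- sum((beta - drop(d$theta %*% xi))^2)
    sig_zeta <- sqrt(1 / stats::rgamma(1, config$a0 + nr / 2,
                                       config$b0 + ss_b / 2))

    # task-2 offsets (optional)
    if (config$task_offset) {
      for (which_off in c("a", "b")) {
        step <- stats::rnorm(1, 0, exp(lsc["off"]))
        if (which_off == "a") {
          cal_p <- exp((a_obs(alpha) + step * d$t2) * d$logc)
          xal_p <- exp((a_obs(alpha) + step * d$t2) * d$logx)
          r_p <- cal_p - w * xal_p
        } else {
          w_p <- weight_fn(d$p, pmin(pmax(b_obs(beta) + step * d$t2, 1e-3), 50))
          r_p <- calpha - w_p * xalpha
        }
        ss_tot_p <- sum(r_p * r_p)
        la <- (sum(ss_i) - ss_tot_p) / (2 * tau^2)
        if (log(stats::runif(1)) < la) {
          if (which_off == "a") {
            d_a <- d_a + step; calpha <- cal_p; xalpha <- xal_p
          } else {
            d_b <- d_b + step; w <- w_p
          }
          ss_i <- drop(rowsum(r_p * r_p, d$resp))
        }
      }
    }

    # global noise ratio tau, loss scale lambda (ridge parameterization)
    ss_tot <- sum(ss_i)
    tau_p <- tau * exp(stats::rnorm(1, 0, exp(lsc["tau"])))
    la <- (-d$n * log(tau_p) - ss_tot / (2 * tau_p^2)) -
      (-d$n * log(tau) - ss_tot / (2 * tau^2)) +
      log_halfnorm(lam * tau_p, priors$sigma_eps[["scale"]]) -
      log_halfnorm(lam * tau, priors$sigma_eps[["scale"]]) +
      log(tau_p) - log(tau)
    a_pr <- min(1, exp(la))
    if (stats::runif(1) < a_pr) tau <- tau_p
    if (adapting) lsc["tau"] <- lsc["tau"] + g_ad * (a_pr - 0.44)

    lam_p <- lam * exp(stats::rnorm(1, 0, exp(lsc["lam"])))
    la <- stats::dlnorm(lam_p, priors$lam[["meanlog"]], priors$lam[["sdlog"]],
                        log = TRUE) -
      stats::dlnorm(lam, priors$lam[["meanlog"]], priors$lam[["sdlog"]],
                    log = TRUE) +
      log_halfnorm(lam_p * tau, priors$sigma_eps[["scale"]]) -
      log_halfnorm(lam * tau, priors$sigma_eps[["scale"]]) +
      2 * (log(lam_p) - log(lam))
    a_pr <- min(1, exp(la))
    if (stats::runif(1) < a_pr) lam <- lam_p
    if (adapting) lsc["lam"] <- lsc["lam"] + g_ad * (a_pr - 0.44)

    if (it > config$n_burn && (it - config$n_burn) %% config$thin == 0L) {
      kept <- kept + 1L
      coef_chains[kept, ] <- c(gam, xi, sig_eta, sig_zeta, lam, lam * tau,
                               if (config$task_offset) c(d_a, d_b))
      asum <- asum + alpha; bsum <- bsum + beta
      edge <- 0.02 * diff(supp)
      a_edge <- a_edge + (alpha < amin + 0.02)
      b_edge <- b_edge + (beta < supp[1] + edge | beta > supp[2] - edge)
    }
  }

  start <- config$n_burn + 1L
  summ <- do.call(rbind, lapply(colnames(coef_chains), function(nm)
    summarize_chain(coef_chains[, nm], start = start, name = nm)))
  respondent <- data.frame(
    respondent_id = d$rid,
    alpha = asum / kept, beta = bsum / kept,
    alpha_boundary = a_edge / kept > 0.25,
    beta_boundary = b_edge / kept > 0.25,
    stringsAsFactors = FALSE)
  rhat <- apply(coef_chains, 2, split_rhat)
  gz <- apply(coef_chains, 2, geweke_z)
  failed <- unique(c(names(rhat)[rhat > 1.05], names(gz)[abs(gz) > 3]))
  if (length(failed))
    cpt_warn(paste("convergence diagnostics failed for:",
                   paste(failed, collapse = ", ")),
             "cpt_convergence_warning")
  fit <- structure(
    list(coef_chains = coef_chains, summary = summ,
         respondent = respondent,
         diagnostics = list(rhat = rhat, geweke_z = gz, failed = failed,
                            converged = length(failed) == 0L,
                            n_boundary = sum(respondent$alpha_boundary |
                                               respondent$beta_boundary)),
         accept = acc / (config$n_iter - config$n_burn),
         config = config),
    class = "cpt_hier_fit")
  fit$report <- flag_significance(fit)
  fit
}

#' @export
print.cpt_hier_fit <- function(x, ...) {
  cat(sprintf("Hierarchical CPT covariate fit: %d respondents, %d retained draws\n",
              nrow(x$respondent), nrow(x$coef_chains)))
  print(x$report, row.names = FALSE, digits = 3)
  if (x$diagnostics$n_boundary > 0)
    cat(sprintf("note: %d respondent(s) at a curvature support edge\n",
                x$diagnostics$n_boundary))
  invisible(x)
}

# point-estimate initialization used by fit_hierarchical; works on the
# value scale, where the observation noise is homoscedastic, so the
# starting point sits in the basin the likelihood favors
init_pair <- function(logc, logx, p, supp, amin) {
  ssq <- function(th) {
    r <- exp(th[1] * logc) - weight_fn(p, th[2]) * exp(th[1] * logx)
    sum(r * r)
  }
  ag <- seq(max(amin, 0.1), 3, length.out = 16)
  bg <- seq(supp[1] + 0.01, supp[2] - 0.01, length.out = 15)
  best <- c(1, 0.7); best_ss <- Inf
  for (b in bg) for (a in ag) {
    ss <- ssq(c(a, b))
    if (ss < best_ss) { best_ss <- ss; best <- c(a, b) }
  }
  stats::optim(best, ssq, method = "L-BFGS-B",
               lower = c(amin, supp[1]), upper = c(5, supp[2]))
}

two_stage_init <- function(d, supp, amin) {
  est <- matrix(NA_real_, d$nr, 2)
  for (i in seq_len(d$nr)) {
    sel <- d$resp == i
    est[i, ] <- init_pair(d$logc[sel], d$logx[sel], d$p[sel], supp, amin)$par
  }
  ga <- stats::lm.fit(d$theta, est[, 1])
  gb <- stats::lm.fit(d$theta, est[, 2])
  pred_c <- weight_fn(d$p, est[d$resp, 2])^(1 / est[d$resp, 1]) * exp(d$logx)
  list(alpha = est[, 1], beta = est[, 2],
       gamma = unname(ga$coefficients), xi = unname(gb$coefficients),
       sigma_eta = stats::sd(ga$residuals), sigma_zeta = stats::sd(gb$residuals),
       tau = stats::sd(exp(d$logc) - pred_c))
}

# The CE-scale objective has a secondary basin (small alpha with large
# beta mimics the opposite corner), so a coarse grid scan chooses the
# basin before the local refinement.
ls_pair <- function(logc, logx, p, supp, amin) {
  cn <- exp(logc); xn <- exp(logx)
  ssq <- function(th) sum((cn - weight_fn(p, th[2])^(1 / th[1]) * xn)^2)
  ag <- seq(max(amin, 0.1), 3, length.out = 16)
  bg <- seq(supp[1] + 0.01, supp[2] - 0.01, length.out = 15)
  best <- c(1, 0.7); best_ss <- Inf
  for (b in bg) {
    w <- weight_fn(p, b)
    for (a in ag) {
      ss <- sum((cn - w^(1 / a) * xn)^2)
      if (ss < best_ss) { best_ss <- ss; best <- c(a, b) }
    }
  }
  stats::optim(best, ssq, method = "L-BFGS-B",
               lower = c(amin, supp[1]), upper = c(5, supp[2]))
}

#' Two-stage cross-check fit of the covariate model
#'
#' Stage 1 estimates \eqn{(\alpha_i, \beta_i)} per respondent by
#' nonlinear least squares of the certainty equivalents on
#' \eqn{w(p)^{1/\alpha} X}; stage 2 regresses the stage-1 estimates on
#' the six coded factors by ordinary least squares. Classical standard
#' errors and p-values come from the stage-2 linear model. Respondents
#' whose stage-1 optimization fails are dropped with a warning; more
#' than 20\% drops is an error.
#'
#' @inheritParams fit_hierarchical
#' @param min_obs minimum observations a respondent must contribute per
#'   task.
#' @return An object of class \code{"cpt_two_stage"}: `gamma` and `xi`
#'   (coefficient matrices with estimate, SE, t, p), `per_respondent`
#'   (stage-1 estimates), `dropped` (respondent ids).
#' @export
two_stage_fit <- function(observations, profiles, tasks, min_obs = 10L) {
  d <- hier_data(observations, profiles, tasks)
  per_task <- table(observations$respondent_id, observations$task_id)
  if (any(per_task < min_obs))
    cpt_abort(sprintf(
      "every respondent must contribute >= %d observations per task", min_obs),
      "cpt_design_error")
  supp <- c(0.3, 2); amin <- 0.05
  est <- matrix(NA_real_, d$nr, 2)
  conv <- logical(d$nr)
  for (i in seq_len(d$nr)) {
    sel <- d$resp == i
    fit <- ls_pair(d$logc[sel], d$logx[sel], d$p[sel], supp, amin)
    est[i, ] <- fit$par
    conv[i] <- fit$convergence == 0
  }
  if (any(!conv)) {
    if (mean(!conv) > 0.2)
      cpt_abort(sprintf("stage-1 fit failed for %.0f%% of respondents",
                        100 * mean(!conv)), "cpt_twostage_error")
    cpt_warn(sprintf("dropping %d respondent(s) with failed stage-1 fits: %s",
                     sum(!conv),
                     paste(utils::head(d$rid[!conv], 5), collapse = ", ")),
             "cpt_twostage_warning")
  }
  keep <- which(conv)
  df <- data.frame(d$theta[keep, -1, drop = FALSE])
  fa <- stats::lm(est[keep, 1] ~ ., data = df)
  fb <- stats::lm(est[keep, 2] ~ ., data = df)
  coef_tab <- function(f) {
    m <- summary(f)$coefficients
    rownames(m) <- coef_terms
    colnames(m) <- c("estimate", "se", "t", "p")
    m
  }
  structure(
    list(gamma = coef_tab(fa), xi = coef_tab(fb),
         per_respondent = data.frame(respondent_id = d$rid,
                                     alpha = est[, 1], beta = est[, 2],
                                     converged = conv,
                                     stringsAsFactors = FALSE),
         dropped = d$rid[!conv]),
    class = "cpt_two_stage")
}

#' Coefficient report with significance flags
#'
#' Builds the standard two-row (\eqn{\alpha}-equation,
#' \eqn{\beta}-equation) coefficient report. For a hierarchical fit a
#' coefficient is flagged \code{"*"} when its central 90\% credible
#' interval excludes zero and \code{"**"} when the 99\% interval does
#' (matched to the classical levels); for a two-stage fit the flags
#' come from two-sided p-values at the same thresholds.
#'
#' @param fit a \code{"cpt_hier_fit"} or \code{"cpt_two_stage"} object.
#' @param levels two significance levels, loosest first.
#' @return A data frame with columns `equation`, `term`, `estimate`,
#'   `lower`, `upper` (90\% interval bounds), `p` (classical route
#'   only), `flag`.
#' @export
flag_significance <- function(fit, levels = c(0.1, 0.01)) {
  if (inherits(fit, "cpt_hier_fit")) {
    rows <- lapply(c("gamma", "xi"), function(eq) {
      prefix <- paste0(eq, "_")
      do.call(rbind, lapply(coef_terms, function(term) {
        ch <- fit$coef_chains[, paste0(prefix, term)]
        ci90 <- stats::quantile(ch, c(levels[1] / 2, 1 - levels[1] / 2),
                                names = FALSE)
        ci99 <- stats::quantile(ch, c(levels[2] / 2, 1 - levels[2] / 2),
                                names = FALSE)
        flag <- if (term != "intercept" && prod(ci99) > 0) "**"
                else if (term != "intercept" && prod(ci90) > 0) "*"
                else ""
        data.frame(equation = if (eq == "gamma") "alpha" else "beta",
                   term = term, estimate = mean(ch),
                   lower = ci90[1], upper = ci90[2], p = NA_real_,
                   flag = flag, stringsAsFactors = FALSE)
      }))
    })
    return(do.call(rbind, rows))
  }
  if (inherits(fit, "cpt_two_stage")) {
    rows <- lapply(c("gamma", "xi"), function(eq) {
      m <- fit[[eq]]
      do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
        term <- rownames(m)[i]
        p <- m[i, "p"]
        flag <- if (term != "intercept" && p < levels[2]) "**"
                else if (term != "intercept" && p < levels[1]) "*"
                else ""
        ci <- m[i, "estimate"] + c(-1, 1) *
          stats::qnorm(1 - levels[1] / 2) * m[i, "se"]
        data.frame(equation = if (eq == "gamma") "alpha" else "beta",
                   term = term, estimate = m[i, "estimate"],
                   lower = ci[1], upper = ci[2], p = p,
                   flag = flag, stringsAsFactors = FALSE)
      }))
    })
    return(do.call(rbind, rows))
  }
  cpt_abort("`fit` must be a cpt_hier_fit or cpt_two_stage object",
            "cpt_type_error")
}
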