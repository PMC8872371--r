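# Run drivers (simulate / fit / regress / recover), manifests, and
# figure generation. Figures are written as PDF vector graphics and
# every curve is also emitted as CSV: the data grids, not the pixels,
# are the testable surface.

ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  invisible(path)
}

write_manifest <- function(out_dir, stage, extra = list()) {
  manifest <- c(
    list(stage = stage,
         package = "cptrisk",
         version = as.character(utils::packageVersion("cptrisk")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    extra)
  path <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"), path)
  invisible(path)
}

#' Simulate a synthetic study and write its artifacts
#'
#' Runs \code{\link{simulate_cohort}} and writes `observations.csv`
#' (instrument schema), `profiles.csv`, `params.csv` (the generating
#' per-respondent curvatures), one `task<k>.json` per task, and a
#' `manifest.json` recording the configuration, seed, and
#' clamping/truncation rates. Output is byte-identical for identical
#' (preset, spec, seed).
#'
#' @inheritParams simulate_cohort
#' @param out_dir output directory (created if needed).
#' @return The \code{\link{simulate_cohort}} result, invisibly.
#' @export
run_simulate <- function(preset = "table2_task1", seed = 1L,
                         out_dir = "cptrisk-run", spec = cohort_spec(),
                         config = NULL, tasks = NULL) {
  ensure_dir(out_dir)
  sim <- simulate_cohort(preset, seed = seed, spec = spec,
                         config = config, tasks = tasks)
  write_observations(sim$observations, file.path(out_dir, "observations.csv"))
  utils::write.csv(sim$profiles, file.path(out_dir, "profiles.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$params, file.path(out_dir, "params.csv"),
                   row.names = FALSE, quote = FALSE)
  for (t in sim$tasks)
    task_to_json(t, file.path(out_dir, sprintf("task%d.json", t$task_id)))
  write_manifest(out_dir, "simulate", list(
    preset = if (is.null(config)) preset else "custom",
    seed = seed,
    n = sim$meta$n,
    n_obs = sim$meta$n_obs,
    gamma = sim$config$gamma, xi = sim$config$xi,
    lam = sim$config$lam, sigma_eps = sim$config$sigma_eps,
    sigma_eta = sim$config$sigma_eta, sigma_zeta = sim$config$sigma_zeta,
    discretize = sim$config$discretize,
    task_ids = vapply(sim$tasks, function(t) t$task_id, integer(1)),
    clamp_rate = sim$meta$clamp_rate,
    n_clamped_alpha = sim$meta$n_clamped_alpha,
    n_clamped_beta = sim$meta$n_clamped_beta,
    truncation_mass = sim$meta$truncation_mass))
  invisible(sim)
}

#' Fit the pooled CPT model and write the standard report
#'
#' Reads observations (CSV path or data frame), fits
#' \code{\link{fit_cpt}}, and writes `summary.csv` with the standard
#' posterior-summary columns (Parameter, Mean, SD, MC_Error, Val2.5pc,
#' Median, Val97.5pc, Start, Sample), `chains.csv` (one column per
#' parameter), `diagnostics.json`, and a manifest.
#'
#' @param observations path to an observations CSV or a validated data
#'   frame.
#' @param task the \code{\link{decision_task}} fitted.
#' @param config an \code{\link{mcmc_config}}.
#' @param out_dir output directory.
#' @return The \code{"cpt_fit"} object, invisibly.
#' @export
run_fit <- function(observations, task, config = mcmc_config(20000, 2000),
                    out_dir = "cptrisk-run") {
  ensure_dir(out_dir)
  if (is.character(observations))
    observations <- read_observations(observations, task)
  if (nrow(observations) == 0L)
    cpt_abort("no observations to fit", "cpt_design_error")
  fit <- fit_cpt(observations, task, config)
  summ <- fit$summary
  names(summ) <- c("Parameter", "Mean", "SD", "MC_Error", "Val2.5pc",
                   "Median", "Val97.5pc", "Start", "Sample")
  utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(fit$chains),
                   file.path(out_dir, "chains.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(jsonlite::toJSON(fit$diagnostics, auto_unbox = TRUE,
                              digits = NA, pretty = TRUE),
             file.path(out_dir, "diagnostics.json"))
  write_manifest(out_dir, "fit", list(
    task_id = task$task_id, money_scale = task$money_scale,
    n_obs = nrow(observations),
    n_iter = config$n_iter, n_burn = config$n_burn, thin = config$thin,
    seed = config$seed, converged = fit$diagnostics$converged))
  invisible(fit)
}

#' Hierarchical covariate regression with the standard coefficient table
#'
#' Fits \code{\link{fit_hierarchical}} and writes `coefficients.csv`
#' in the published two-row layout (one row per equation, one column
#' per factor, estimates annotated with significance flags),
#' `coefficients_full.json` with the full posterior uncertainty, and a
#' manifest.
#'
#' @param observations path to an observations CSV or a data frame.
#' @param profiles path to a profiles CSV or a data frame.
#' @param tasks task list referenced by the observations.
#' @param config a \code{\link{hier_config}}.
#' @param out_dir output directory.
#' @return The \code{"cpt_hier_fit"} object, invisibly.
#' @export
run_regress <- function(observations, profiles, tasks = default_tasks(),
                        config = hier_config(), out_dir = "cptrisk-run") {
  ensure_dir(out_dir)
  if (is.character(observations))
    observations <- read_observations(observations, tasks)
  if (is.character(profiles))
    profiles <- utils::read.csv(profiles, stringsAsFactors = FALSE,
                                colClasses = c(respondent_id = "character"))
  fit <- fit_hierarchical(observations, profiles, tasks, config)
  rep <- fit$report
  wide <- do.call(rbind, lapply(split(rep, rep$equation), function(block) {
    vals <- sprintf("%.3g%s", block$estimate, block$flag)
    out <- as.data.frame(as.list(vals), stringsAsFactors = FALSE)
    names(out) <- c("theta0", "Gender", "Job.Title", "Funding.Status",
                    "LTCF.Type", "Facility.Scale", "Strategy.Type")
    cbind(Parameter = block$equation[1], out)
  }))
  utils::write.csv(wide, file.path(out_dir, "coefficients.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(jsonlite::toJSON(
    list(report = fit$report, summary = fit$summary,
         diagnostics = fit$diagnostics[c("rhat", "geweke_z", "converged",
                                         "n_boundary")]),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"),
    file.path(out_dir, "coefficients_full.json"))
  write_manifest(out_dir, "regress", list(
    n_respondents = nrow(fit$respondent),
    n_obs = nrow(observations),
    n_iter = config$n_iter, n_burn = config$n_burn, seed = config$seed,
    task_offset = config$task_offset,
    converged = fit$diagnostics$converged))
  invisible(fit)
}

#' End-to-end parameter-recovery experiment
#'
#' For each seed: simulate a cohort under the preset, fit the pooled
#' model (homogeneous presets) or the hierarchical model (`table3` /
#' `null`), and tabulate generating value, posterior mean, and bias per
#' parameter. Writes `recovery.csv` and a manifest.
#'
#' @inheritParams run_simulate
#' @param seeds integer vector of simulation seeds.
#' @param fit_config an \code{\link{mcmc_config}} or
#'   \code{\link{hier_config}} matching the preset's fit route.
#' @return Data frame of recovery results, invisibly.
#' @export
run_recover <- function(preset = "table2_task1", seeds = 1:3,
                        fit_config = NULL, spec = cohort_spec(),
                        out_dir = "cptrisk-run") {
  ensure_dir(out_dir)
  hier <- preset %in% c("table3", "null")
  rows <- list()
  for (s in seeds) {
    sim <- simulate_cohort(preset, seed = s, spec = spec)
    if (hier) {
      cfg <- fit_config %||% hier_config(seed = s)
      cfg$seed <- as.integer(s)
      fit <- fit_hierarchical(sim$observations, sim$profiles, sim$tasks, cfg)
      truth <- c(paste0("gamma_", coef_terms), paste0("xi_", coef_terms))
      tv <- c(sim$config$gamma, sim$config$xi)
      pm <- colMeans(fit$coef_chains[, truth])
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, parameter = truth, truth = tv, posterior_mean = pm,
        bias = pm - tv, stringsAsFactors = FALSE)
    } else {
      cfg <- fit_config %||% mcmc_config(20000, 2000, seed = s)
      cfg$seed <- as.integer(s)
      task <- sim$tasks[[1]]
      fit <- fit_cpt(sim$observations, task, cfg)
      truth <- c(alpha = sim$config$gamma[1], beta = sim$config$xi[1])
      pm <- colMeans(fit$chains[, names(truth)])
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, parameter = names(truth), truth = unname(truth),
        posterior_mean = unname(pm), bias = unname(pm - truth),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(out_dir, "recovery.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, "recover",
                 list(preset = preset, seeds = seeds))
  invisible(out)
}

#' Plot the value and weighting functions of a task
#'
#' Writes a two-panel PDF per task — \eqn{v(x)} over the task's loss
#' range (normalized money) and \eqn{w(p)} over [0, 1] with the
#' identity diagonal — plus `vf_curve.csv` and `pwf_curve.csv` holding
#' the exact plotted grids.
#'
#' @param params a \code{\link{cpt_params}}.
#' @param task a \code{\link{decision_task}}.
#' @param out_dir output directory.
#' @param n_grid number of grid points per curve.
#' @return Named list of written file paths; the curve data frames are
#'   attached as attributes `vf` and `pwf`.
#' @export
plot_cpt_functions <- function(params, task, out_dir = "cptrisk-run",
                               n_grid = 512L) {
  stopifnot(inherits(params, "cpt_params"), inherits(task, "decision_task"))
  ensure_dir(out_dir)
  xmax <- max(task$losses_usd) / task$money_scale
  xg <- seq(-xmax, 0, length.out = n_grid)
  vf <- data.frame(x = xg, v = cpt_value(xg, params))
  pg <- seq(0, 1, length.out = n_grid)
  pwf <- data.frame(p = pg, w = cpt_weight(pg, params), identity = pg)
  vf_csv <- file.path(out_dir, sprintf("vf_curve_task%d.csv", task$task_id))
  pwf_csv <- file.path(out_dir, sprintf("pwf_curve_task%d.csv", task$task_id))
  utils::write.csv(vf, vf_csv, row.names = FALSE, quote = FALSE)
  utils::write.csv(pwf, pwf_csv, row.names = FALSE, quote = FALSE)
  pdf_path <- file.path(out_dir, sprintf("cpt_functions_task%d.pdf",
                                         task$task_id))
  grDevices::pdf(pdf_path, width = 9, height = 4.5)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(4.2, 4.2, 2.5, 1))
  graphics::plot(vf$x, vf$v, type = "l", lwd = 2, col = "steelblue4",
                 xlab = "normalized outcome x", ylab = "v(x)",
                 main = sprintf("Value function, task %d", task$task_id))
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  graphics::plot(pwf$p, pwf$w, type = "l", lwd = 2, col = "firebrick",
                 xlab = "probability p", ylab = "w(p)",
                 main = sprintf("Weighting function, task %d", task$task_id))
  graphics::abline(0, 1, col = "grey60", lty = 2)
  out <- list(pdf = pdf_path, vf_csv = vf_csv, pwf_csv = pwf_csv)
  attr(out, "vf") <- vf
  attr(out, "pwf") <- pwf
  out
}

#' Plot posterior densities of MCMC chains
#'
#' One kernel-density panel per parameter, written as a PDF, with the
#' evaluated density grids emitted as `posterior_density.csv`
#' (columns: parameter, x, density). A constant chain falls back to a
#' degenerate single-bin histogram representation instead of a kernel
#' density.
#'
#' @param chains matrix of MCMC draws, one named column per parameter.
#' @param out_dir output directory.
#' @return Named list of written file paths with the density grid
#'   attached as attribute `grid`.
#' @export
plot_posterior_densities <- function(chains, out_dir = "cptrisk-run") {
  if (is.null(dim(chains)) || nrow(chains) == 0L)
    cpt_abort("`chains` must be a non-empty matrix", "cpt_chain_error")
  ensure_dir(out_dir)
  grids <- lapply(colnames(chains), function(nm) {
    ch <- chains[, nm]
    if (stats::sd(ch) == 0) {
      # degenerate spike: unit mass in a narrow bin around the value
      eps <- max(abs(ch[1]) * 1e-6, 1e-12)
      data.frame(parameter = nm,
                 x = ch[1] + c(-eps, 0, eps),
                 density = c(0, 1 / (2 * eps), 0),
                 stringsAsFactors = FALSE)
    } else {
      dd <- stats::density(ch)
      data.frame(parameter = nm, x = dd$x, density = dd$y,
                 stringsAsFactors = FALSE)
    }
  })
  grid <- do.call(rbind, grids)
  csv_path <- file.path(out_dir, "posterior_density.csv")
  utils::write.csv(grid, csv_path, row.names = FALSE, quote = FALSE)
  pdf_path <- file.path(out_dir, "posterior_density.pdf")
  grDevices::pdf(pdf_path, width = 8, height = 6)
  on.exit(grDevices::dev.off())
  k <- length(grids)
  graphics::par(mfrow = c(ceiling(k / 2), min(k, 2)),
                mar = c(4, 4, 2.5, 1))
  for (g in grids)
    graphics::plot(g$x, g$density, type = "l", lwd = 2, col = "steelblue4",
                   xlab = g$parameter[1], ylab = "density",
                   main = g$parameter[1])
  out <- list(pdf = pdf_path, csv = csv_path)
  attr(out, "grid") <- grid
  out
}
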