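#' Behavioral parameters of the loss-domain CPT model
#'
#' Bundles the four parameters of the certainty-equivalent observation
#' model: the loss scale \eqn{\lambda} of the value function
#' \eqn{v(X) = -\lambda(-X)^\alpha} (on normalized money), the value
#' curvature \eqn{\alpha}, the probability-weighting curvature
#' \eqn{\beta} of \eqn{w(p) = p^\beta / (p^\beta + (1-p)^\beta)^{1/\beta}},
#' and the standard deviation \eqn{\sigma_\epsilon} of the Gaussian
#' error on the value scale.
#'
#' The one-parameter weighting function loses monotonicity for
#' \eqn{\beta} below roughly 0.28, so \code{beta} is restricted to a
#' configurable support whose default \code{c(0.3, 2)} excludes the
#' non-monotone region; a non-monotone support is rejected at
#' construction time.
#'
#' @param lam loss scale \eqn{\lambda > 0} (dimensionless on normalized
#'   money).
#' @param alpha value curvature \eqn{\alpha > 0}; \eqn{\alpha > 1} means
#'   risk aversion on losses of this size, \eqn{\alpha = 1} linear value.
#' @param beta weighting curvature; \eqn{\beta < 1} overweights small and
#'   underweights large probabilities, \eqn{\beta = 1} is linear.
#' @param sigma_eps value-scale error SD, \eqn{\ge 0}.
#' @param beta_support numeric length-2 vector, the closed support
#'   allowed for \code{beta}.
#' @return An object of class \code{"cpt_params"}.
#' @examples
#' cpt_params(lam = 1.091, alpha = 1.433, beta = 0.525)
#' @export
cpt_params <- function(lam = 1, alpha = 1, beta = 1, sigma_eps = 0,
                       beta_support = c(0.3, 2)) {
  stopifnot_scalar_number(lam, "lam")
  stopifnot_scalar_number(alpha, "alpha")
  stopifnot_scalar_number(beta, "beta")
  stopifnot_scalar_number(sigma_eps, "sigma_eps")
  check_beta_support(beta_support)
  if (lam <= 0) cpt_abort("`lam` must be > 0", "cpt_param_error")
  if (alpha <= 0) cpt_abort("`alpha` must be > 0", "cpt_param_error")
  if (sigma_eps < 0) cpt_abort("`sigma_eps` must be >= 0", "cpt_param_error")
  if (beta < beta_support[1] || beta > beta_support[2])
    cpt_abort(sprintf("`beta` = %g outside support [%g, %g]",
                      beta, beta_support[1], beta_support[2]),
              "cpt_param_error")
  structure(
    list(lam = lam, alpha = alpha, beta = beta, sigma_eps = sigma_eps,
         beta_support = beta_support),
    class = "cpt_params"
  )
}

#' Check that a weighting-curvature support keeps w(p) monotone
#'
#' Verifies numerically (on a probability grid of step \code{1e-3}) that
#' the weighting function is strictly increasing at the lower end of the
#' proposed support, where monotonicity is lost first.
#'
#' @param support numeric length-2 vector, candidate \code{beta} support.
#' @return `support`, invisibly; aborts if the support admits a
#'   non-monotone weighting function.
#' @export
check_beta_support <- function(support) {
  if (!is.numeric(support) || length(support) != 2L || any(!is.finite(support)))
    cpt_abort("`beta_support` must be two finite numbers", "cpt_param_error")
  if (support[1] >= support[2] || support[1] <= 0)
    cpt_abort("`beta_support` must satisfy 0 < lower < upper",
              "cpt_param_error")
  p <- seq(1e-3, 1 - 1e-3, by = 1e-3)
  w <- weight_fn(p, support[1])
  if (any(diff(w) <= 0))
    cpt_abort(sprintf(
      "beta support lower bound %g makes w(p) non-monotone", support[1]),
      "cpt_support_error")
  invisible(support)
}

#' @export
print.cpt_params <- function(x, ...) {
  cat("CPT parameters (loss domain)\n")
  cat(sprintf("  lambda    %.4g\n  alpha     %.4g\n  beta      %.4g\n  sigma_eps %.4g\n",
              x$lam, x$alpha, x$beta, x$sigma_eps))
  cat(sprintf("  beta support [%g, %g]\n", x$beta_support[1], x$beta_support[2]))
  invisible(x)
}

#' Serialize CPT parameters to JSON
#'
#' @param params a \code{\link{cpt_params}} object.
#' @param path optional file path; when given the JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "cpt_params"))
  js <- jsonlite::toJSON(
    list(lam = params$lam, alpha = params$alpha, beta = params$beta,
         sigma_eps = params$sigma_eps, beta_support = params$beta_support),
    auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read CPT parameters from JSON
#'
#' @param x a JSON string or a path to a JSON file.
#' @return A \code{\link{cpt_params}} object.
#' @export
params_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  support <- obj$beta_support %||% c(0.3, 2)
  cpt_params(lam = obj$lam, alpha = obj$alpha, beta = obj$beta,
             sigma_eps = obj$sigma_eps %||% 0, beta_support = support)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
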