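# Pure CPT mathematics on the loss domain: value function, probability
# weighting function, the certainty-equivalent identity, and inverses.
# All money entering these functions is normalized (USD / money_scale).

# bare workhorses, free of class checks, used throughout the samplers
value_fn <- function(x, lam, alpha) {
  v <- -lam * (-x)^alpha
  v[x == 0] <- 0  # v(0) := 0 by continuity
  v
}

weight_fn <- function(p, beta) {
  pb <- p^beta
  qb <- (1 - p)^beta
  w <- pb / (pb + qb)^(1 / beta)
  w[p == 0] <- 0
  w[p == 1] <- 1
  w
}

#' Loss-domain value function
#'
#' Computes \eqn{v(x) = -\lambda(-x)^\alpha} for normalized money
#' \eqn{x \le 0}, with \eqn{v(0) = 0} by continuity. Gains are outside
#' this model and are rejected.
#'
#' @param x numeric vector of normalized monetary outcomes, all
#'   \eqn{\le 0}.
#' @param params a \code{\link{cpt_params}} object.
#' @return Numeric vector of prospect values (unitless, \eqn{\le 0}).
#' @examples
#' p <- cpt_params(lam = 2, alpha = 1)
#' cpt_value(c(0, -1), p)   # 0, -2
#' @export
cpt_value <- function(x, params) {
  stopifnot(inherits(params, "cpt_params"))
  if (any(!is.finite(x)) || any(x > 0))
    cpt_abort("`x` must be finite and <= 0 (loss domain only)",
              "cpt_domain_error")
  value_fn(x, params$lam, params$alpha)
}

#' Inverse of the loss-domain value function
#'
#' Maps a prospect value \eqn{vv \le 0} back to normalized money:
#' \eqn{x = -(-vv/\lambda)^{1/\alpha}}, so that
#' \code{cpt_value(cpt_value_inverse(vv)) == vv} to relative tolerance
#' \code{1e-10}.
#'
#' @param vv numeric vector of prospect values, all \eqn{\le 0}.
#' @inheritParams cpt_value
#' @return Numeric vector of normalized money (\eqn{\le 0}).
#' @export
cpt_value_inverse <- function(vv, params) {
  stopifnot(inherits(params, "cpt_params"))
  if (any(!is.finite(vv)) || any(vv > 0))
    cpt_abort("`vv` must be finite and <= 0", "cpt_domain_error")
  value_inverse_fn(vv, params$lam, params$alpha)
}

value_inverse_fn <- function(vv, lam, alpha) {
  x <- -(-vv / lam)^(1 / alpha)
  x[vv == 0] <- 0
  x
}

#' Probability weighting function
#'
#' The one-parameter inverse-S weighting function
#' \eqn{w(p) = p^\beta / (p^\beta + (1-p)^\beta)^{1/\beta}} with
#' \eqn{w(0) = 0} and \eqn{w(1) = 1}. For \eqn{\beta < 1} small
#' probabilities are overweighted and large ones underweighted; at
#' \eqn{\beta = 1} it reduces to the identity.
#'
#' @param p numeric vector of probabilities in \eqn{[0, 1]}.
#' @inheritParams cpt_value
#' @return Numeric vector of decision weights in \eqn{[0, 1]}.
#' @examples
#' p <- cpt_params(beta = 0.525)
#' cpt_weight(c(0.01, 0.5, 0.99), p)
#' @export
cpt_weight <- function(p, params) {
  stopifnot(inherits(params, "cpt_params"))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    cpt_abort("`p` must lie in [0, 1]", "cpt_domain_error")
  weight_fn(p, params$beta)
}

#' Predicted certainty equivalent of a binary loss prospect
#'
#' Solves the certainty-equivalent identity
#' \eqn{v(CE) = w(p)\,v(-X) + (1 - w(p))\,v(0)} for a prospect that
#' loses \code{loss_usd} with probability \code{p} and nothing
#' otherwise. On the loss domain the solution is
#' \eqn{CE = w(p)^{1/\alpha} \cdot X}: the loss scale \eqn{\lambda}
#' cancels, and the predicted CE always lies strictly between 0 and the
#' loss.
#'
#' @param p probability of the loss, in \eqn{(0, 1)} (vectorized).
#' @param loss_usd positive loss magnitude in USD (vectorized).
#' @param task a \code{\link{decision_task}}; supplies the monetary
#'   normalization (the prediction itself is scale-free).
#' @inheritParams cpt_value
#' @return Predicted certainty equivalents in USD.
#' @examples
#' t1 <- default_tasks()[[1]]
#' ce_predict(0.1, 40000, t1, cpt_params(alpha = 1, beta = 1))  # 4000
#' @export
ce_predict <- function(p, loss_usd, task, params) {
  stopifnot(inherits(params, "cpt_params"), inherits(task, "decision_task"))
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    cpt_abort("`p` must lie in (0, 1)", "cpt_domain_error")
  if (any(!is.finite(loss_usd)) || any(loss_usd <= 0))
    cpt_abort("`loss_usd` must be > 0", "cpt_domain_error")
  weight_fn(p, params$beta)^(1 / params$alpha) * loss_usd
}
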