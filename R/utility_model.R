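#' @keywords internal
#' @noRd
hara_shifted_income <- function(y, S, params, what = "utility") {
  z <- y - params$omega - params$theta * S
  if (any(!is.finite(z)) || any(z <= 0)) {
    bad <- which(!is.finite(z) | z <= 0)
    stop(sprintf(
      "domain violation in %s: y - omega - theta*S must be positive (first offending index %d: y = %.4g, S = %d)",
      what, bad[1L], y[bad[1L]], as.integer(S[bad[1L]])
    ), call. = FALSE)
  }
  z
}

#' Predicted life satisfaction under the state-dependent HARA model
#'
#' Evaluates
#' \eqn{\alpha + \frac{\beta}{1-\gamma}((y-\omega-\theta S)/\gamma)^{1-\gamma}
#' + \delta S + \tau'X} at the given income and sickness state. For
#' `gamma = 1` the expression is replaced by the logarithmic branch
#' (see [log_branch_utility()]); the objective is non-smooth across that
#' boundary, so the two branches are kept explicit rather than taking a
#' numerical limit.
#'
#' The function is strictly increasing in `y` on its domain, and for
#' `gamma > 1` it is bounded above by `alpha + delta*S + controls_effect`.
#'
#' @param y Net income, thousand EUR/yr. Vectorised.
#' @param S Sickness indicator, 0 or 1. Vectorised (recycled with `y`).
#' @param params A [utility_params()] object.
#' @param controls_effect Additive contribution of the controls,
#'   life-satisfaction points (scalar or vector). Default 0.
#' @return Predicted life satisfaction (same length as `y`).
#' @export
evaluate_utility <- function(y, S, params, controls_effect = 0) {
  stopifnot(inherits(params, "utility_params"))
  if (params$gamma == 1) {
    return(log_branch_utility(y, S, params, controls_effect))
  }
  z <- hara_shifted_income(y, S, params, "evaluate_utility")
  params$alpha +
    params$beta / (1 - params$gamma) * (z / params$gamma)^(1 - params$gamma) +
    params$delta * S + controls_effect
}

#' Marginal utility of income
#'
#' Returns \eqn{u'(y, S) = (\beta/\gamma)((y-\omega-\theta S)/\gamma)^{-\gamma}},
#' in life-satisfaction points per thousand EUR. Positive and decreasing
#' in income for `beta > 0`. The same expression is exact for the
#' logarithmic branch (`gamma = 1` gives `beta / (y - omega - theta*S)`).
#'
#' A positive fixed cost of sickness makes marginal utility higher in the
#' sick state at every income.
#'
#' @inheritParams evaluate_utility
#' @return Marginal utility (same length as `y`).
#' @export
marginal_utility <- function(y, S, params) {
  stopifnot(inherits(params, "utility_params"))
  z <- hara_shifted_income(y, S, params, "marginal_utility")
  params$beta / params$gamma * (z / params$gamma)^(-params$gamma)
}

#' Relative risk aversion of the state-dependent HARA model
#'
#' \eqn{RRA(y, S) = -y u''/u' = \gamma y / (y - \omega - \theta S)}.
#' With `omega + theta*S < 0` this is increasing in income and converges
#' to `gamma` from below as income grows; at `omega = theta = 0` it
#' reduces to the CRRA constant `gamma`.
#'
#' @inheritParams evaluate_utility
#' @return Dimensionless relative risk aversion.
#' @export
relative_risk_aversion <- function(y, S, params) {
  stopifnot(inherits(params, "utility_params"))
  z <- hara_shifted_income(y, S, params, "relative_risk_aversion")
  params$gamma * y / z
}

#' Relative prudence of the state-dependent HARA model
#'
#' \eqn{RP(y, S) = -y u'''/u'' = (\gamma+1) y / (y - \omega - \theta S)},
#' the ratio `RP/RRA = (gamma+1)/gamma` holding at every valid point.
#'
#' @inheritParams evaluate_utility
#' @return Dimensionless relative prudence.
#' @export
relative_prudence <- function(y, S, params) {
  stopifnot(inherits(params, "utility_params"))
  z <- hara_shifted_income(y, S, params, "relative_prudence")
  (params$gamma + 1) * y / z
}

#' Logarithmic branch of the utility model (gamma = 1)
#'
#' \eqn{\alpha + \beta \log(y - \omega - \theta S) + \delta S + \tau'X}.
#' Its implied relative risk aversion is `y / (y - omega - theta*S)`,
#' consistent with the HARA closed form at `gamma = 1`.
#'
#' @inheritParams evaluate_utility
#' @return Predicted life satisfaction (same length as `y`).
#' @export
log_branch_utility <- function(y, S, params, controls_effect = 0) {
  stopifnot(inherits(params, "utility_params"))
  z <- hara_shifted_income(y, S, params, "log_branch_utility")
  params$alpha + params$beta * log(z) + params$delta * S + controls_effect
}

#' Controls contribution implied by a parameter set
#'
#' Computes `tau' X` for the recognised control columns of a panel. An
#' empty `tau` gives 0.
#'
#' @param panel A panel data frame (see [simulate_panel()]).
#' @param params A [utility_params()] object.
#' @return Numeric vector, one value per panel row.
#' @export
controls_effect <- function(panel, params) {
  stopifnot(inherits(params, "utility_params"))
  tau <- params$tau
  if (!length(tau)) return(rep(0, nrow(panel)))
  X <- control_matrix(panel)
  unknown <- setdiff(names(tau), colnames(X))
  if (length(unknown)) {
    stop("unrecognised control coefficients: ", paste(unknown, collapse = ", "))
  }
  drop(X[, names(tau), drop = FALSE] %*% tau)
}

# design matrix of the standard control set
#' @noRd
control_matrix <- function(panel) {
  cbind(age = panel$age,
        age_sq = panel$age^2,
        household_size = panel$household_size,
        female = panel$female,
        married = panel$married)
}
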