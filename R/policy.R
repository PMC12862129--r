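#' Policy configuration for optimal replacement-rate schedules
#'
#' Bundles the utility parameters with the behavioral inputs of the
#' augmented Baily-Chetty condition: the sum of the extensive-margin
#' odds elasticity and the duration elasticity of sickness absence with
#' respect to the benefit, supplied as a single constant (default 1.5),
#' and the income grid on which to evaluate the schedule.
#'
#' @param params A [utility_params()] object.
#' @param elasticity_sum Nonnegative moral-hazard elasticity sum.
#' @param income_grid Ascending net incomes, thousand EUR/yr.
#' @return An object of class `policy_config`.
#' @export
policy_config <- function(params, elasticity_sum = 1.5,
                          income_grid = seq(10, 120, by = 1)) {
  stopifnot(inherits(params, "utility_params"),
            is.numeric(elasticity_sum), length(elasticity_sum) == 1L,
            elasticity_sum >= 0,
            length(income_grid) >= 1L, all(diff(income_grid) > 0))
  structure(list(params = params, elasticity_sum = elasticity_sum,
                 income_grid = income_grid),
            class = "policy_config")
}

#' Exact marginal-utility gap between sickness states
#'
#' The proportional gap \eqn{u'(c_s, 1)/u'(c_e, 0) - 1 =
#' ((c_s-\omega-\theta)/(c_e-\omega))^{-\gamma} - 1}: the value-of-
#' insurance side of the Baily-Chetty condition. Zero when there is no
#' consumption drop and no state dependence; strictly increasing as
#' sick-state consumption falls.
#'
#' @param ce Healthy-state consumption (net income), thousand EUR/yr.
#' @param cs Sick-state consumption, thousand EUR/yr.
#' @param params A [utility_params()] object.
#' @return Dimensionless gap (vectorised over `ce`/`cs`).
#' @export
mu_gap_exact <- function(ce, cs, params) {
  stopifnot(inherits(params, "utility_params"))
  ze <- hara_shifted_income(ce, 0, params, "mu_gap_exact (healthy state)")
  zs <- hara_shifted_income(cs, 1, params, "mu_gap_exact (sick state)")
  (zs / ze)^(-params$gamma) - 1
}

#' Second-order approximation to the marginal-utility gap
#'
#' \eqn{RRA(c_e, 0)\, x\, (1 + \tfrac12 RP(c_e, 0)\, x)} with
#' \eqn{x = (\Delta c + \theta)/c_e}: the gap expressed through relative
#' risk aversion and relative prudence in the healthy state. Agrees with
#' [mu_gap_exact()] through second order in `x` (the remainder vanishes
#' at cubic rate).
#'
#' @inheritParams mu_gap_exact
#' @return Dimensionless approximate gap.
#' @export
mu_gap_approx <- function(ce, cs, params) {
  stopifnot(inherits(params, "utility_params"))
  hara_shifted_income(ce, 0, params, "mu_gap_approx (healthy state)")
  hara_shifted_income(cs, 1, params, "mu_gap_approx (sick state)")
  x <- (ce - cs + params$theta) / ce
  rra <- relative_risk_aversion(ce, 0, params)
  rp <- relative_prudence(ce, 0, params)
  rra * x * (1 + 0.5 * rp * x)
}

#' Optimal sickness-insurance replacement rate
#'
#' Closed-form solution of the augmented Baily-Chetty condition under
#' the state-dependent HARA model:
#' \deqn{RR = \frac{\omega}{y_e} + \frac{\theta}{y_e} +
#'   \left(1 - \frac{\omega}{y_e}\right)(1 + \epsilon)^{-1/\gamma},}
#' where \eqn{\epsilon} is the moral-hazard elasticity sum. The implied
#' sick-state income `RR * ye` makes the exact marginal-utility gap
#' equal \eqn{\epsilon} exactly. At `omega = theta = 0` this reduces to
#' the income-independent CRRA rate \eqn{(1+\epsilon)^{-1/\gamma}}, and
#' at \eqn{\epsilon = 0}, `theta = 0` to full insurance (`RR = 1`).
#'
#' @param ye Healthy-state net income, thousand EUR/yr (vectorised).
#' @param elasticity_sum Nonnegative moral-hazard elasticity sum.
#' @param params A [utility_params()] object.
#' @return The optimal replacement rate.
#' @export
optimal_replacement_rate <- function(ye, elasticity_sum, params) {
  stopifnot(inherits(params, "utility_params"),
            is.numeric(elasticity_sum), length(elasticity_sum) == 1L,
            elasticity_sum >= 0)
  hara_shifted_income(ye, 0, params, "optimal_replacement_rate")
  rr <- params$omega / ye + params$theta / ye +
    (1 - params$omega / ye) * (1 + elasticity_sum)^(-1 / params$gamma)
  ys <- rr * ye
  if (any(ys <= params$omega + params$theta)) {
    stop("infeasible: implied sick-state income is outside the utility domain")
  }
  rr
}

#' Optimal replacement-rate schedule over an income grid
#'
#' Evaluates the optimal replacement rate, the implied sick-state
#' income, state-specific relative risk aversion and both
#' marginal-utility gap measures at each grid income, together with a
#' `theta = 0` counterfactual column that isolates the contribution of
#' the fixed cost of sickness. Grid points where the schedule is
#' infeasible are recorded as such (`feasible = FALSE`, values `NA`)
#' and the curve continues.
#'
#' @param config A [policy_config()] object.
#' @return A data frame with one row per grid income: `income`,
#'   `optimal_rr`, `rr_theta0`, `ys`, `rra_healthy`, `rra_sick`,
#'   `mu_gap_exact`, `mu_gap_approx`, `feasible`; the attribute
#'   `increasing` reports whether the feasible part of the schedule is
#'   nondecreasing in income.
#' @export
policy_curve <- function(config) {
  stopifnot(inherits(config, "policy_config"))
  params <- config$params
  params0 <- utility_params(alpha = params$alpha, beta = params$beta,
                            gamma = params$gamma, omega = params$omega,
                            theta = 0, delta = params$delta,
                            tau = params$tau)
  eps <- config$elasticity_sum
  out <- lapply(config$income_grid, function(ye) {
    row <- data.frame(income = ye, optimal_rr = NA_real_,
                      rr_theta0 = NA_real_, ys = NA_real_,
                      rra_healthy = NA_real_, rra_sick = NA_real_,
                      mu_gap_exact = NA_real_, mu_gap_approx = NA_real_,
                      feasible = FALSE)
    tryCatch({
      rr <- optimal_replacement_rate(ye, eps, params)
      ys <- rr * ye
      row$optimal_rr <- rr
      row$ys <- ys
      row$rra_healthy <- relative_risk_aversion(ye, 0, params)
      row$rra_sick <- relative_risk_aversion(ye, 1, params)
      row$mu_gap_exact <- mu_gap_exact(ye, ys, params)
      row$mu_gap_approx <- mu_gap_approx(ye, ys, params)
      row$feasible <- TRUE
      row
    }, error = function(e) row)
    }
  )
  curve <- do.call(rbind, out)
  for (i in seq_len(nrow(curve))) {
    curve$rr_theta0[i] <- tryCatch(
      optimal_replacement_rate(curve$income[i], eps, params0),
      error = function(e) NA_real_)
  }
  feas <- curve$optimal_rr[curve$feasible]
  attr(curve, "increasing") <- length(feas) < 2L || all(diff(feas) >= 0)
  curve
}
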