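#' State-dependent HARA utility parameters
#'
#' Bundles the parameters of the state-dependent HARA life-satisfaction
#' model
#' \deqn{u(y, S) = \alpha + \frac{\beta}{1-\gamma}
#'   \left(\frac{y - \omega - \theta S}{\gamma}\right)^{1-\gamma}
#'   + \delta S + \tau'X,}
#' where `y` is net income in thousand EUR/yr and `S` the sickness
#' indicator.
#'
#' The scale parameter \eqn{\beta} is conventionally *printed* in
#' "thousands": a printed value of 2.79 corresponds to an internal value of
#' 2790 when income is measured in thousand EUR. All model code works on
#' the internal scale; use `beta_scale = "printed"` to enter printed
#' values, and [printed_beta()] to read estimates back on the printed
#' scale.
#'
#' @param alpha Constant level (life-satisfaction points).
#' @param beta Scale parameter; internal scale unless
#'   `beta_scale = "printed"`.
#' @param gamma Curvature, must be positive. `gamma = 1` selects the
#'   logarithmic branch of the model.
#' @param omega Institutions parameter: common horizontal shift,
#'   thousand EUR. Negative values imply baseline protection at low
#'   incomes and relative risk aversion increasing in income.
#' @param theta Fixed cost of sickness: horizontal shift in the sick
#'   state, thousand EUR. `theta > 0` means higher marginal utility when
#'   sick (positive state dependence).
#' @param delta Level effect of sickness (life-satisfaction points).
#' @param tau Named numeric vector of control coefficients; may be empty.
#'   Recognised names: `age`, `age_sq`, `household_size`, `female`,
#'   `married`.
#' @param beta_scale Either `"internal"` (default) or `"printed"`.
#'
#' @return An object of class `utility_params`.
#' @examples
#' utility_params(alpha = 9.93, beta = 2.79, gamma = 3.19,
#'                omega = -56.49, theta = 4.86, delta = -0.21,
#'                beta_scale = "printed")
#' @export
utility_params <- function(alpha, beta, gamma, omega, theta = 0, delta = 0,
                           tau = numeric(0),
                           beta_scale = c("internal", "printed")) {
  beta_scale <- match.arg(beta_scale)
  for (v in list(alpha, beta, gamma, omega, theta, delta)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("all scalar parameters must be single finite numbers")
    }
  }
  if (gamma <= 0) stop("gamma must be positive")
  if (length(tau) > 0 && is.null(names(tau))) {
    stop("tau must be a named numeric vector")
  }
  if (beta_scale == "printed") beta <- beta * 1000
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, omega = omega,
         theta = theta, delta = delta, tau = tau),
    class = "utility_params"
  )
}

#' Read the scale parameter on the printed ("thousands") scale
#'
#' @param params A [utility_params()] object.
#' @return The printed-scale beta (internal beta / 1000).
#' @export
printed_beta <- function(params) {
  stopifnot(inherits(params, "utility_params"))
  params$beta / 1000
}

#' @export
print.utility_params <- function(x, ...) {
  cat("State-dependent HARA utility parameters\n")
  cat(sprintf("  alpha = %.4g   beta = %.4g (printed %.4g)   gamma = %.4g\n",
              x$alpha, x$beta, x$beta / 1000, x$gamma))
  cat(sprintf("  omega = %.4g   theta = %.4g   delta = %.4g\n",
              x$omega, x$theta, x$delta))
  if (length(x$tau)) {
    cat("  controls:", paste(sprintf("%s=%.4g", names(x$tau), x$tau),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reference parameter sets for the German switcher-sample analysis
#'
#' Published point estimates of the state-dependent HARA model on the
#' German Socio-Economic Panel (SOEP) switcher subsample, used as
#' simulator defaults, starting-point anchors and worked-example inputs.
#' `"main"` is the main specification (with individual controls and year
#' effects); `"no_controls"` is the same model without controls.
#'
#' @param which Which specification to return.
#' @return A [utility_params()] object (internal beta scale).
#' @export
hara_reference_params <- function(which = c("main", "no_controls")) {
  which <- match.arg(which)
  switch(which,
    main = utility_params(alpha = 9.93, beta = 2.79, gamma = 3.19,
                          omega = -56.49, theta = 4.86, delta = -0.21,
                          beta_scale = "printed"),
    no_controls = utility_params(alpha = 7.75, beta = 2.10, gamma = 3.09,
                                 omega = -57.95, theta = 6.28,
                                 delta = -0.17, beta_scale = "printed")
  )
}
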