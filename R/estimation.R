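#' Published default starting values for the utility fit
#'
#' `{alpha = 10, beta = 0, gamma = 2.7, omega = -15, theta = 15,
#' delta = 0}`, with zeros for all control and year coefficients. `beta`
#' is on the printed scale (0 is 0 on either scale).
#'
#' @return Named numeric vector of starting values.
#' @export
default_start <- function() {
  c(alpha = 10, beta = 0, gamma = 2.7, omega = -15, theta = 15, delta = 0)
}

# names of the structural parameters, in reporting order
#' @noRd
base_param_names <- c("alpha", "beta", "gamma", "omega", "theta", "delta")

# assemble the design pieces the residual function needs
#' @noRd
build_design <- function(panel, use_controls, use_year_effects, use_weights,
                         model) {
  validate_panel(panel)
  if (nrow(panel) == 0L) stop("panel is empty")
  w <- if (use_weights) panel$weight else rep(1, nrow(panel))
  d <- list(
    y = panel$net_income,
    S = panel$sick,
    ls = panel$life_satisfaction,
    # normalized to mean one: estimates, SEs and the residual SE are then
    # invariant to rescaling all weights by a positive constant
    w = w / mean(w),
    model = model
  )
  d$Xlin <- NULL
  lin_names <- character(0)
  if (use_controls) {
    Xc <- control_matrix(panel)
    colnames(Xc) <- paste0("ctrl_", colnames(Xc))
    d$Xlin <- Xc
    lin_names <- colnames(Xc)
  }
  if (use_year_effects) {
    yrs <- sort(unique(panel$year))
    if (length(yrs) > 1L) {
      Xy <- stats::model.matrix(~ factor(panel$year))[, -1L, drop = FALSE]
      colnames(Xy) <- paste0("yr_", yrs[-1L])
      d$Xlin <- if (is.null(d$Xlin)) Xy else cbind(d$Xlin, Xy)
      lin_names <- c(lin_names, colnames(Xy))
    }
  }
  d$par_names <- c(base_param_names, lin_names)
  d
}

# model prediction for a full named parameter vector; returns NULL when
# the parameter vector leaves the valid domain
#' @noRd
predict_design <- function(p, d) {
  z <- d$y - p["omega"] - p["theta"] * d$S
  if (any(z <= 0)) return(NULL)
  if (d$model == "power") {
    g <- p["gamma"]
    if (g <= 0 || abs(g - 1) < 1e-8) return(NULL)
    core <- p["alpha"] + p["beta"] / (1 - g) * (z / g)^(1 - g) +
      p["delta"] * d$S
  } else {
    core <- p["alpha"] + p["beta"] * log(z) + p["delta"] * d$S
  }
  if (!is.null(d$Xlin)) {
    core <- core + drop(d$Xlin %*% p[colnames(d$Xlin)])
  }
  if (any(!is.finite(core))) return(NULL)
  core
}

#' Weighted nonlinear least-squares fit of the utility model
#'
#' Minimises the weighted sum of squared deviations between observed
#' life satisfaction and the state-dependent HARA prediction, using
#' Levenberg-Marquardt damped least squares ([minpack.lm::nls.lm()]).
#' Trial parameter vectors that violate the domain
#' `y - omega - theta*S > 0` for any observation (or `gamma <= 0`, or a
#' non-finite prediction) receive a finite penalty of ten times the last
#' valid objective value, so the damped search can retreat instead of
#' failing.
#'
#' Convergence is declared when the relative change in the objective or
#' the step norm falls below `1e-10` (at most 1000 iterations);
#' non-convergence is reported via `converged = FALSE`, not an error.
#'
#' @param panel A panel data frame (see [simulate_panel()]).
#' @param start Named numeric vector of starting values on the internal
#'   beta scale (defaults to [default_start()]); missing control/year
#'   coefficients start at zero. A [utility_params()] object is also
#'   accepted.
#' @param model `"power"` for the HARA branch, `"log"` for the
#'   logarithmic branch (`gamma` fixed at 1).
#' @param use_controls Include age, age squared, household size, female
#'   and married as free linear coefficients.
#' @param use_year_effects Include calendar-year dummy coefficients
#'   (baseline: first year).
#' @param use_weights Weight observations by the sampling weights.
#' @param fix Optional named numeric vector of parameters to hold fixed
#'   (e.g. `c(theta = 0)`).
#' @param control Optional overrides for
#'   [minpack.lm::nls.lm.control()].
#' @return An object of class `hara_fit`: estimated `params`
#'   ([utility_params()]), full `coefficients`, `standard_errors`,
#'   `sse`, `residual_se`, `n`, `converged`, `iterations`,
#'   `start_values`, `regime`, `year_effects`, `rsstrace` (objective
#'   value at each accepted step) and the fitting `spec`.
#' @export
fit_utility_nls <- function(panel, start = default_start(),
                            model = c("power", "log"),
                            use_controls = FALSE, use_year_effects = FALSE,
                            use_weights = TRUE, fix = NULL,
                            control = list()) {
  model <- match.arg(model)
  if (inherits(start, "utility_params")) {
    start <- c(alpha = start$alpha, beta = start$beta, gamma = start$gamma,
               omega = start$omega, theta = start$theta, delta = start$delta,
               if (length(start$tau)) stats::setNames(start$tau, paste0("ctrl_", names(start$tau))))
  }
  d <- build_design(panel, use_controls, use_year_effects, use_weights, model)
  if (model == "log") {
    fix <- c(fix, c(gamma = 1))
    fix <- fix[!duplicated(names(fix))]
  }
  free <- setdiff(d$par_names, names(fix))
  if (any(c("theta", "delta") %in% free) && length(unique(d$S)) < 2L) {
    stop("theta/delta are not identified: panel contains a single sickness state")
  }
  if (nrow(panel) <= length(free)) {
    stop("more free parameters than observations")
  }
  p0 <- stats::setNames(rep(0, length(d$par_names)), d$par_names)
  p0[intersect(names(start), d$par_names)] <-
    start[intersect(names(start), d$par_names)]
  if (length(fix)) p0[names(fix)] <- fix

  sqw <- sqrt(d$w)
  n <- length(d$y)
  penalty_env <- new.env(parent = emptyenv())
  penalty_env$last_sse <-
    sum(d$w * (d$ls - stats::weighted.mean(d$ls, d$w))^2)
  resid_fn <- function(pfree) {
    p <- p0
    p[free] <- pfree
    mu <- predict_design(p, d)
    if (is.null(mu)) {
      return(rep(sqrt(10 * penalty_env$last_sse / n), n))
    }
    r <- sqw * (d$ls - mu)
    penalty_env$last_sse <- sum(r^2)
    r
  }
  ctrl <- utils::modifyList(
    list(maxiter = 1000, ftol = 1e-10, ptol = 1e-10, maxfev = 200000,
         nprint = 0),
    control)
  lm_fit <- minpack.lm::nls.lm(
    par = p0[free], fn = resid_fn,
    control = do.call(minpack.lm::nls.lm.control, ctrl))

  coefs <- p0
  coefs[free] <- coef(lm_fit)
  tau_names <- grep("^ctrl_", d$par_names, value = TRUE)
  params <- utility_params(
    alpha = coefs[["alpha"]], beta = coefs[["beta"]],
    gamma = max(coefs[["gamma"]], .Machine$double.eps),
    omega = coefs[["omega"]], theta = coefs[["theta"]],
    delta = coefs[["delta"]],
    tau = if (length(tau_names))
      stats::setNames(coefs[tau_names], sub("^ctrl_", "", tau_names))
    else numeric(0))

  fit <- structure(list(
    params = params,
    coefficients = coefs,
    free = free,
    sse = lm_fit$deviance,
    residual_se = sqrt(lm_fit$deviance / (n - length(free))),
    n = n,
    converged = lm_fit$info %in% 1:4,
    iterations = lm_fit$niter,
    info = lm_fit$info,
    message = lm_fit$message,
    rsstrace = lm_fit$rsstrace,
    start_values = p0,
    regime = NA_character_,
    year_effects = if (any(startsWith(d$par_names, "yr_")))
      coefs[grep("^yr_", d$par_names)] else NULL,
    spec = list(model = model, use_controls = use_controls,
                use_year_effects = use_year_effects,
                use_weights = use_weights, fix = fix)
  ), class = "hara_fit")
  fit$standard_errors <- standard_errors(fit, panel)
  fit
}

#' @export
print.hara_fit <- function(x, ...) {
  cat(sprintf("State-dependent HARA utility fit (%s branch)%s\n",
              x$spec$model,
              if (!is.na(x$regime)) sprintf(" [regime: %s]", x$regime) else ""))
  est <- x$coefficients[base_param_names]
  se <- x$standard_errors[base_param_names]
  stars <- vapply(2 * stats::pnorm(-abs(est / se)), function(p) {
    if (is.na(p)) "" else if (p < 0.01) "***" else if (p < 0.05) "**"
    else if (p < 0.1) "*" else ""
  }, character(1))
  out <- data.frame(estimate = round(est, 4), se = round(se, 4),
                    sig = stars)
  out["beta", "estimate"] <- round(printed_beta(x$params), 4)
  rownames(out)[rownames(out) == "beta"] <- "beta (printed)"
  out["beta (printed)", "se"] <- round(se[["beta"]] / 1000, 4)
  print(out)
  cat(sprintf("n = %d, SSE = %.4g, residual SE = %.4g, converged = %s (%d iterations)\n",
              x$n, x$sse, x$residual_se, x$converged, x$iterations))
  invisible(x)
}

#' Gauss-Newton standard errors of a converged fit
#'
#' Square roots of the diagonal of
#' \eqn{\hat\sigma^2 (J'WJ)^{-1}}, with `J` the Jacobian of the model
#' prediction at the optimum (central differences), `W` the sampling
#' weights and \eqn{\hat\sigma^2} the weighted residual variance. The
#' information matrix is column-scaled before inversion; if it is
#' singular even after scaling, the affected standard errors are
#' returned as `NA` (flagged, never fabricated) with a warning.
#'
#' @param fit A `hara_fit` object.
#' @param panel The panel the fit was computed on.
#' @return Named vector of standard errors for all parameters (fixed
#'   parameters get `NA`).
#' @export
standard_errors <- function(fit, panel) {
  stopifnot(inherits(fit, "hara_fit"))
  d <- build_design(panel, fit$spec$use_controls, fit$spec$use_year_effects,
                    fit$spec$use_weights, fit$spec$model)
  free <- fit$free
  p <- fit$coefficients
  n <- length(d$y)
  sqw <- sqrt(d$w)
  J <- matrix(NA_real_, n, length(free))
  for (j in seq_along(free)) {
    h <- 1e-6 * (abs(p[[free[j]]]) + 1e-4)
    up <- p; up[free[j]] <- up[free[j]] + h
    dn <- p; dn[free[j]] <- dn[free[j]] - h
    mu_up <- predict_design(up, d)
    mu_dn <- predict_design(dn, d)
    if (is.null(mu_up) && is.null(mu_dn)) {
      warning("optimum on the domain boundary; standard errors undefined")
      return(stats::setNames(rep(NA_real_, length(p)), names(p)))
    }
    # fall back to a one-sided difference at a domain boundary
    if (is.null(mu_up) || is.null(mu_dn)) {
      mu0 <- predict_design(p, d)
      J[, j] <- if (is.null(mu_up)) sqw * (mu0 - mu_dn) / h
                else sqw * (mu_up - mu0) / h
    } else {
      J[, j] <- sqw * (mu_up - mu_dn) / (2 * h)
    }
  }
  A <- crossprod(J)
  dscale <- sqrt(diag(A))
  se_free <- rep(NA_real_, length(free))
  ok <- dscale > 0
  if (any(ok)) {
    As <- A[ok, ok, drop = FALSE] / tcrossprod(dscale[ok])
    inv <- tryCatch(solve(As), error = function(e) NULL)
    if (is.null(inv) || any(diag(inv) < 0)) {
      warning("singular information matrix; standard errors undefined")
    } else {
      sigma2 <- fit$sse / (n - length(free))
      se_free[ok] <- sqrt(diag(inv) * sigma2) / dscale[ok]
    }
  }
  se <- stats::setNames(rep(NA_real_, length(p)), names(p))
  se[free] <- se_free
  se
}

#' Multi-start fit with curvature-regime selection
#'
#' The SSE surface of the HARA fit is non-smooth across `gamma = 1` and
#' can have regime-dependent optima, so the fit is restarted from the
#' published default start (`gamma = 2.7`), one start in the low
#' (`gamma < 1`) and high (`gamma > 3.5`) curvature regimes, and the
#' logarithmic branch (`gamma = 1`). The converged fit with the lowest
#' weighted SSE wins; exact ties are broken toward the default regime,
#' then toward smaller `gamma`.
#'
#' @param panel A panel data frame.
#' @param regime_starts Optional list of starts, each a list with
#'   elements `start` (named numeric), `model` (`"power"` or `"log"`)
#'   and `regime` (label). Defaults to the four starts described above.
#' @param ... Passed to [fit_utility_nls()] (`use_controls`,
#'   `use_weights`, ...).
#' @return The winning `hara_fit`, with `regime` set and a `candidates`
#'   data frame (per-start regime, SSE, convergence, gamma) attached.
#' @export
multi_start_fit <- function(panel, regime_starts = NULL, ...) {
  if (is.null(regime_starts)) {
    s0 <- default_start()
    regime_starts <- list(
      list(start = s0, model = "power", regime = "default"),
      list(start = replace(s0, "gamma", 0.5), model = "power",
           regime = "gamma_low"),
      list(start = replace(s0, "gamma", 5), model = "power",
           regime = "gamma_high"),
      list(start = s0, model = "log", regime = "log")
    )
  }
  if (!length(regime_starts)) stop("need at least one start")
  fits <- vector("list", length(regime_starts))
  for (i in seq_along(regime_starts)) {
    rs <- regime_starts[[i]]
    fits[[i]] <- tryCatch({
      f <- fit_utility_nls(panel, start = rs$start, model = rs$model, ...)
      f$regime <- rs$regime
      f
    }, error = function(e) e)
  }
  ok <- vapply(fits, function(f) inherits(f, "hara_fit") && f$converged,
               logical(1))
  cand <- data.frame(
    regime = vapply(regime_starts, `[[`, character(1), "regime"),
    model = vapply(regime_starts, `[[`, character(1), "model"),
    converged = ok,
    sse = vapply(fits, function(f)
      if (inherits(f, "hara_fit")) f$sse else NA_real_, numeric(1)),
    gamma = vapply(fits, function(f)
      if (inherits(f, "hara_fit")) f$params$gamma else NA_real_, numeric(1)),
    residual_se = vapply(fits, function(f)
      if (inherits(f, "hara_fit")) f$residual_se else NA_real_, numeric(1))
  )
  if (!any(ok)) {
    msgs <- vapply(seq_along(fits), function(i) {
      f <- fits[[i]]
      sprintf("%s: %s", cand$regime[i],
              if (inherits(f, "error")) conditionMessage(f)
              else paste("not converged;", f$message))
    }, character(1))
    stop("no start converged:\n", paste(msgs, collapse = "\n"))
  }
  sse <- cand$sse
  best_sse <- min(sse[ok])
  # optima agreeing in SSE to well under the convergence tolerance count
  # as ties and go to the default regime, then to smaller gamma
  tied <- which(ok & sse <= best_sse * (1 + 1e-9))
  if (length(tied) > 1L) {
    pri <- order(cand$regime[tied] != "default", cand$gamma[tied])
    winner_i <- tied[pri[1L]]
  } else {
    winner_i <- tied
  }
  winner <- fits[[winner_i]]
  winner$candidates <- cand
  winner
}

#' Sensitivity of the fit to starting values
#'
#' Refits the model over a grid of starting values for one parameter,
#' holding the other starts at `base_start`, and records the full
#' converged estimate vector and SSE at each grid point. A fit is
#' flagged unstable when the range of any structural estimate across
#' converged fits exceeds `stability_tol` relative to its typical
#' magnitude.
#'
#' @param panel A panel data frame.
#' @param param_name Name of the start parameter to vary.
#' @param grid Numeric vector of starting values (nonempty).
#' @param base_start Baseline start vector (default [default_start()]).
#' @param stability_tol Relative range above which an estimate is
#'   flagged unstable (default `1e-3`).
#' @param ... Passed to [fit_utility_nls()].
#' @return A data frame with one row per grid point (start value,
#'   convergence, SSE and every structural estimate) with attributes
#'   `stable` (logical) and `unstable_params` (character).
#' @export
starting_value_sweep <- function(panel, param_name, grid,
                                 base_start = default_start(),
                                 stability_tol = 1e-3, ...) {
  if (!length(grid)) stop("grid must be nonempty")
  if (!param_name %in% names(base_start)) {
    stop("unknown start parameter: ", param_name)
  }
  rows <- lapply(grid, function(g) {
    st <- replace(base_start, param_name, g)
    f <- tryCatch(fit_utility_nls(panel, start = st, ...),
                  error = function(e) NULL)
    if (is.null(f)) {
      out <- data.frame(start_value = g, converged = FALSE, sse = NA_real_)
      out[base_param_names] <- NA_real_
      return(out)
    }
    out <- data.frame(start_value = g, converged = f$converged, sse = f$sse)
    out[base_param_names] <- as.list(f$coefficients[base_param_names])
    out
  })
  res <- do.call(rbind, rows)
  conv <- res[res$converged %in% TRUE, , drop = FALSE]
  unstable <- character(0)
  if (nrow(conv) > 1L) {
    for (pn in base_param_names) {
      rng <- diff(range(conv[[pn]]))
      if (rng / (1 + abs(stats::median(conv[[pn]]))) > stability_tol) {
        unstable <- c(unstable, pn)
      }
    }
  }
  attr(res, "stable") <- length(unstable) == 0L
  attr(res, "unstable_params") <- unstable
  res
}

#' Binarize the life-satisfaction outcome
#'
#' Replaces life satisfaction by the indicator
#' `life_satisfaction >= cutoff` (the boundary value maps to 1),
#' leaving all other columns untouched. Used to probe sensitivity of
#' the state-dependence estimate to treating the 0-10 scale as a binary
#' happiness measure.
#'
#' @param panel A panel data frame.
#' @param cutoff Cutoff on the 0-10 scale (typical choices: 6 to 9).
#' @return The panel with a binarized outcome.
#' @export
binarize_outcome <- function(panel, cutoff) {
  validate_panel(panel)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 ||
      cutoff > 10) {
    stop("cutoff must be a single value in [0, 10]")
  }
  panel$life_satisfaction <- as.numeric(panel$life_satisfaction >= cutoff)
  panel
}
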