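test_that("noise-free data returns the generating parameters essentially exactly", {
  truth <- hara_reference_params("main")
  panel <- small_panel(n_ind = 400, seed = 17, noise_sd = 0)
  fit <- fit_utility_nls(panel, start = default_start())
  expect_true(fit$converged)
  expect_lt(fit$sse, 1e-10)
  est <- fit$coefficients
  for (nm in c("alpha", "beta", "gamma", "omega", "theta", "delta")) {
    expect_equal(est[[nm]], truth[[nm]], tolerance = 1e-4)
  }
})

test_that("with theta fixed at zero and no sick effect, delta is estimated near zero", {
  p0 <- utility_params(alpha = 9.93, beta = 2790, gamma = 3.19,
                       omega = -56.49, theta = 0, delta = 0)
  panel <- small_panel(n_ind = 400, seed = 23, noise_sd = 0.5, params = p0)
  fit <- fit_utility_nls(panel, fix = c(theta = 0))
  expect_true(fit$converged)
  expect_true(is.na(fit$standard_errors[["theta"]]))
  expect_lt(abs(fit$coefficients[["delta"]]),
            2 * fit$standard_errors[["delta"]])
})

test_that("estimates and standard errors are invariant to weight rescaling", {
  panel <- small_panel(n_ind = 250, seed = 29, noise_sd = 0.4)
  f1 <- fit_utility_nls(panel)
  panel2 <- panel
  panel2$weight <- panel$weight * 7.3
  f2 <- fit_utility_nls(panel2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  expect_equal(f1$standard_errors, f2$standard_errors, tolerance = 1e-6)
})

test_that("duplicating every observation shrinks standard errors by about sqrt 2", {
  panel <- small_panel(n_ind = 250, seed = 29, noise_sd = 0.8)
  doubled <- rbind(panel, panel)
  f1 <- fit_utility_nls(panel)
  f2 <- fit_utility_nls(doubled)
  ratio <- f2$standard_errors[f2$free] / f1$standard_errors[f1$free]
  expect_equal(unname(ratio), rep(1 / sqrt(2), length(ratio)),
               tolerance = 0.05)
})

test_that("Gauss-Newton standard errors agree with a nonparametric bootstrap", {
  truth <- hara_reference_params("main")
  panel <- small_panel(n_ind = 180, seed = 37, noise_sd = 0.15)
  fit <- fit_utility_nls(panel, start = truth)
  set.seed(99)
  boot <- suppressWarnings(replicate(200, {
    idx <- sample.int(nrow(panel), replace = TRUE)
    bf <- tryCatch(
      fit_utility_nls(panel[idx, ], start = fit$coefficients,
                      control = list(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(bf) || !bf$converged) rep(NA_real_, 2)
    else c(bf$coefficients[["theta"]], bf$coefficients[["alpha"]])
  }))
  boot_se <- apply(boot, 1, sd, na.rm = TRUE)
  expect_equal(fit$standard_errors[["theta"]], boot_se[1], tolerance = 0.2)
  expect_equal(fit$standard_errors[["alpha"]], boot_se[2], tolerance = 0.2)
})

test_that("the linear submodel reproduces textbook weighted-OLS estimates and SEs", {
  truth <- hara_reference_params("main")
  panel <- small_panel(n_ind = 200, seed = 41, noise_sd = 0.6)
  fixed <- c(gamma = truth$gamma, omega = truth$omega, theta = truth$theta)
  fit <- fit_utility_nls(panel, start = truth, fix = fixed)
  # alpha, beta, delta enter linearly once the shape is fixed
  z <- (panel$net_income - truth$omega - truth$theta * panel$sick) /
    truth$gamma
  k <- z^(1 - truth$gamma) / (1 - truth$gamma)
  ols <- lm(life_satisfaction ~ k + sick, data = panel,
            weights = panel$weight)
  cf <- summary(ols)$coefficients
  expect_equal(fit$coefficients[["alpha"]], cf["(Intercept)", "Estimate"],
               tolerance = 1e-6)
  expect_equal(fit$coefficients[["beta"]], cf["k", "Estimate"],
               tolerance = 1e-6)
  expect_equal(fit$coefficients[["delta"]], cf["sick", "Estimate"],
               tolerance = 1e-6)
  expect_equal(fit$standard_errors[["alpha"]],
               cf["(Intercept)", "Std. Error"], tolerance = 1e-4)
  expect_equal(fit$standard_errors[["beta"]], cf["k", "Std. Error"],
               tolerance = 1e-4)
  expect_equal(fit$standard_errors[["delta"]], cf["sick", "Std. Error"],
               tolerance = 1e-4)
})

test_that("multi-start selection returns the lowest-SSE converged regime", {
  panel <- small_panel(n_ind = 500, seed = 47, noise_sd = 1.0)
  fit <- suppressWarnings(multi_start_fit(panel))
  cand <- fit$candidates
  expect_true(fit$converged)
  expect_true(all(fit$sse <= cand$sse[cand$converged] * (1 + 1e-12)))
  # data generated from the curved branch: the log branch fits worse
  log_rse <- cand$residual_se[cand$regime == "log"]
  expect_true(is.na(log_rse) || log_rse > fit$residual_se)
  expect_false(fit$regime == "log")
})

test_that("accepted Levenberg-Marquardt steps never increase the objective", {
  panel <- small_panel(n_ind = 300, seed = 53, noise_sd = 1.2)
  fit <- suppressWarnings(fit_utility_nls(panel))
  trace <- fit$rsstrace
  expect_gt(length(trace), 3)
  expect_true(all(diff(trace) <= 1e-8 * trace[-length(trace)]))
})

test_that("refitting from the optimum stays at the optimum", {
  panel <- small_panel(n_ind = 400, seed = 59, noise_sd = 0.3)
  fit <- fit_utility_nls(panel)
  refit <- fit_utility_nls(panel, start = fit$coefficients)
  expect_equal(refit$coefficients[refit$free], fit$coefficients[fit$free],
               tolerance = 1e-3)
  expect_lte(refit$sse, fit$sse * (1 + 1e-10))
})

test_that("starting-value sweeps flag stability correctly", {
  panel <- small_panel(n_ind = 300, seed = 61, noise_sd = 0.3)
  sweep_a <- starting_value_sweep(panel, "alpha", c(5, 10, 15))
  expect_true(all(sweep_a$converged))
  expect_true(attr(sweep_a, "stable"))
  expect_equal(max(sweep_a$theta) - min(sweep_a$theta), 0, tolerance = 1e-4)

  single <- starting_value_sweep(panel, "gamma", 2.7)
  expect_equal(nrow(single), 1)

  sweep_g <- suppressWarnings(
    starting_value_sweep(panel, "gamma", c(0.5, 2.7, 5)))
  expect_equal(nrow(sweep_g), 3)
  expect_true(all(c("sse", "gamma", "converged") %in% names(sweep_g)))
  expect_error(starting_value_sweep(panel, "gamma", numeric(0)), "nonempty")
  expect_error(starting_value_sweep(panel, "nope", 1), "unknown")
})

test_that("binarization uses the >= rule and touches nothing else", {
  panel <- toy_panel(person_id = c(1, 1, 2, 2), net_income = c(40, 41, 39, 38),
                     sick = c(0, 1, 0, 1),
                     life_satisfaction = c(6, 5.9, 10, 0))
  b6 <- binarize_outcome(panel, 6)
  expect_equal(b6$life_satisfaction, c(1, 0, 1, 0))
  b0 <- binarize_outcome(panel, 0)
  expect_equal(b0$life_satisfaction, rep(1, 4))
  expect_equal(b6[setdiff(names(b6), "life_satisfaction")],
               panel[setdiff(names(panel), "life_satisfaction")])
  expect_error(binarize_outcome(panel, 11), "cutoff")
  expect_error(binarize_outcome(panel, -1), "cutoff")
})

test_that("single-state panels are rejected when state parameters are free", {
  panel <- small_panel(n_ind = 150, seed = 67, sick_prob_mean = 0)
  expect_error(fit_utility_nls(panel), "identified")
  # but fine with both state parameters pinned
  fit <- fit_utility_nls(panel, fix = c(theta = 0, delta = 0))
  expect_true(fit$converged)
})

test_that("a degenerate design yields flagged, not fabricated, standard errors", {
  panel <- small_panel(n_ind = 200, seed = 71, noise_sd = 0.5)
  panel$female <- 0L  # constant control: its column carries no information
  fit <- fit_utility_nls(panel, use_controls = TRUE)
  expect_true(is.na(fit$standard_errors[["ctrl_female"]]))
  expect_true(is.finite(fit$standard_errors[["theta"]]))
})
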