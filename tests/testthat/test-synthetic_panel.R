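test_that("a fixed seed reproduces the panel exactly", {
  cfg <- synthetic_config(n_individuals = 150, seed = 42)
  expect_identical(simulate_panel(cfg), simulate_panel(cfg))
  cfg2 <- synthetic_config(n_individuals = 150, seed = 43)
  expect_false(identical(simulate_panel(cfg), simulate_panel(cfg2)))
})

test_that("without noise the outcome equals the model prediction exactly", {
  tau <- c(age = 0.002, household_size = -0.01, female = 0.05)
  p <- utility_params(alpha = 9.5, beta = 2790, gamma = 3.19,
                      omega = -56.49, theta = 4.86, delta = -0.21, tau = tau)
  panel <- small_panel(n_ind = 120, seed = 9, noise_sd = 0, params = p)
  mu <- evaluate_utility(panel$net_income, panel$sick, p,
                         controls_effect(panel, p))
  expect_equal(panel$life_satisfaction, mu, tolerance = 1e-14)
})

test_that("degenerate sickness propensities behave as configured", {
  none <- simulate_panel(synthetic_config(n_individuals = 100, seed = 2,
                                          sick_prob_mean = 0))
  expect_true(all(none$sick == 0))
  all_sick <- simulate_panel(synthetic_config(n_individuals = 50, seed = 2,
                                              sick_prob_mean = 1))
  expect_true(all(all_sick$sick == 1))
})

test_that("calibrated generator hits the target sample moments", {
  # switcher-subsample moments averaged over 10 seeds, within 5% of the
  # calibration targets: healthy mean income 47.43, SD 28.6 (thousand
  # EUR/yr), sick share 16.3%, ~9.6 periods per individual
  moments <- sapply(1:10, function(s) {
    panel <- filter_switchers(simulate_panel(
      synthetic_config(n_individuals = 2500, seed = s)))
    healthy <- panel[panel$sick == 0, ]
    c(mean_inc = mean(healthy$net_income),
      sd_inc = sd(healthy$net_income),
      sick_share = mean(panel$sick),
      periods = nrow(panel) / length(unique(panel$person_id)))
  })
  avg <- rowMeans(moments)
  expect_equal(avg[["mean_inc"]], 47.43, tolerance = 0.05)
  expect_equal(avg[["sd_inc"]], 28.6, tolerance = 0.05)
  expect_equal(avg[["sick_share"]], 0.163, tolerance = 0.05)
  expect_equal(avg[["periods"]], 9.6, tolerance = 0.05)
})

test_that("switcher filtering keeps exactly the mixed-state individuals", {
  panel <- toy_panel(
    person_id = c(1, 1, 2, 2, 3, 3, 3),
    net_income = c(40, 42, 38, 39, 45, 44, 46),
    sick = c(0, 0, 1, 1, 0, 1, 0),
    life_satisfaction = c(7, 7, 6, 6, 7, 6, 7)
  )
  kept <- filter_switchers(panel)
  expect_equal(unique(kept$person_id), 3)
  expect_equal(nrow(kept), 3)  # all person-years of the switcher retained
  # idempotent
  expect_equal(filter_switchers(kept), kept)
  # an individual with one sick and one healthy year survives whole
  pair <- toy_panel(person_id = c(9, 9), net_income = c(40, 41),
                    sick = c(1, 0), life_satisfaction = c(6, 7))
  expect_equal(nrow(filter_switchers(pair)), 2)
  # degenerate input: warning and empty result
  expect_warning(out <- filter_switchers(panel[panel$person_id == 1, ]),
                 "no switchers")
  expect_equal(nrow(out), 0)
})

test_that("sick-year incomes are the healthy counterfactual scaled down", {
  cfg_drop <- synthetic_config(n_individuals = 200, seed = 5,
                               sick_income_drop = 0.04)
  cfg_none <- synthetic_config(n_individuals = 200, seed = 5,
                               sick_income_drop = 0)
  with_drop <- simulate_panel(cfg_drop)
  without <- simulate_panel(cfg_none)
  sick <- with_drop$sick == 1
  expect_equal(with_drop$net_income[sick], 0.96 * without$net_income[sick],
               tolerance = 1e-14)
  expect_equal(with_drop$net_income[!sick], without$net_income[!sick],
               tolerance = 1e-14)
})

test_that("generated outcomes regress on the model mean with unit slope", {
  cfg <- synthetic_config(n_individuals = 2000, seed = 12, noise_sd = 0.8)
  panel <- simulate_panel(cfg)
  mu <- evaluate_utility(panel$net_income, panel$sick, cfg$true_params)
  fit <- lm(panel$life_satisfaction ~ mu)
  cf <- summary(fit)$coefficients
  expect_lt(abs(cf["mu", "Estimate"] - 1), 3 * cf["mu", "Std. Error"] + 1e-8)
  expect_lt(abs(cf["(Intercept)", "Estimate"]),
            3 * cf["(Intercept)", "Std. Error"] + 1e-8)
})

test_that("incompatible configs fail loudly instead of truncating", {
  bad <- synthetic_config(
    n_individuals = 60, seed = 3,
    true_params = utility_params(alpha = 7, beta = 1000, gamma = 2,
                                 omega = 40, theta = 5))
  expect_error(simulate_panel(bad), "domain violated at person")
  # noise-free predictions outside the 0-10 scale are an error when the
  # outcome is left continuous
  high <- synthetic_config(
    n_individuals = 60, seed = 3, noise_sd = 0,
    true_params = utility_params(alpha = 11, beta = 2790, gamma = 3.19,
                                 omega = -56.49))
  expect_error(simulate_panel(high), "outside \\[0, 10\\]")
  # but rounding mode clips
  rounded <- simulate_panel(synthetic_config(
    n_individuals = 60, seed = 3, round_outcome = TRUE))
  expect_true(all(rounded$life_satisfaction %in% 0:10))
})

test_that("descriptive summary reproduces construction-level quantities", {
  two <- toy_panel(person_id = c(1, 2), net_income = c(40, 40),
                   sick = c(0, 1), life_satisfaction = c(6, 8))
  s <- summarize_panel(two)
  expect_equal(mean(s$by_state$ls_mean), 7)

  panel <- filter_switchers(small_panel(n_ind = 2500, seed = 31,
                                        noise_sd = 1.6))
  s <- summarize_panel(panel)
  expect_equal(s$by_state$state, c("healthy", "sick"))
  expect_equal(s$n_individuals, length(unique(panel$person_id)))
  # configured 4% sick-year income reduction shows up in the summary
  expect_equal(s$income_gap, 0.04, tolerance = 0.25)
  # healthy-minus-sick life-satisfaction gap near its model value (~0.32)
  mu <- evaluate_utility(panel$net_income, panel$sick,
                         hara_reference_params("main"))
  model_gap <- mean(mu[panel$sick == 0]) - mean(mu[panel$sick == 1])
  expect_equal(s$ls_gap, model_gap, tolerance = 0.35)
})

test_that("panels round-trip through CSV", {
  panel <- small_panel(n_ind = 40, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_equal(back, panel, tolerance = 1e-12)
})
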