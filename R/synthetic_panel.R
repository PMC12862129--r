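#' Configuration for the synthetic panel generator
#'
#' The generator emulates a screened person-year employment panel of the
#' kind the state-dependent utility analysis is designed for: a German
#' Socio-Economic Panel (SOEP)-like sample of working-age individuals
#' with net income, a more-than-six-weeks sickness-absence indicator, a
#' 0-10 life-satisfaction score, sampling weights and basic demographic
#' controls.
#'
#' Defaults are calibrated so that the `filter_switchers()` subsample of
#' a default draw matches the published switcher-sample moments: about
#' 7,000 individuals and 67,000 person-years of which about 16.5% are
#' sick years, healthy-state net income with mean 47.4 and SD 28.6
#' thousand EUR/yr, and a roughly 4% lower mean income in sick years.
#'
#' Income is lognormal with a persistent individual component
#' (`income_log_mean`, `income_log_sd`) and a mean-one within-person
#' year shock (`income_year_sd`); sick years' incomes are reduced by the
#' fraction `sick_income_drop` relative to the same person-year's healthy
#' counterfactual. Sickness propensity is an individual-level Beta draw
#' (mean `sick_prob_mean`, concentration `sick_prob_concentration`) with
#' independent Bernoulli year outcomes, which produces a realistic
#' switcher composition.
#'
#' @param n_individuals Number of individuals in the screened population
#'   (before any switcher filtering).
#' @param years_per_individual Mean panel length in years; individual
#'   lengths are Poisson draws truncated below at 2.
#' @param income_log_mean,income_log_sd Lognormal parameters of the
#'   persistent individual income component (thousand EUR/yr).
#' @param income_year_sd Lognormal sd of the mean-one within-person year
#'   shock.
#' @param sick_prob_mean,sick_prob_concentration Beta parameters
#'   (mean/concentration form) of the individual sickness propensity.
#' @param sick_income_drop Proportional income reduction in sick years,
#'   in `[0, 1)`.
#' @param true_params [utility_params()] used to generate life
#'   satisfaction.
#' @param noise_sd SD of the additive Gaussian life-satisfaction noise
#'   (life-satisfaction points).
#' @param round_outcome If `TRUE`, round life satisfaction to integers
#'   and clip to `[0, 10]` (survey realism); if `FALSE` (default) leave
#'   it continuous, which is the right setting for estimator recovery
#'   studies since rounding and clipping bias nonlinear least squares.
#' @param seed Integer RNG seed; a fixed seed gives a byte-identical
#'   panel.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_individuals = 17600,
                             years_per_individual = 9,
                             income_log_mean = 3.72404,
                             income_log_sd = 0.5198,
                             income_year_sd = 0.2,
                             sick_prob_mean = 0.07,
                             sick_prob_concentration = 15,
                             sick_income_drop = 0.04,
                             true_params = hara_reference_params("main"),
                             noise_sd = 1.6,
                             round_outcome = FALSE,
                             seed = 1L) {
  stopifnot(n_individuals >= 1, years_per_individual > 0,
            income_log_sd >= 0, income_year_sd >= 0, noise_sd >= 0,
            sick_prob_mean >= 0, sick_prob_mean <= 1,
            sick_prob_concentration > 0,
            sick_income_drop >= 0, sick_income_drop < 1,
            inherits(true_params, "utility_params"),
            is.finite(seed))
  structure(
    list(n_individuals = as.integer(n_individuals),
         years_per_individual = years_per_individual,
         income_log_mean = income_log_mean,
         income_log_sd = income_log_sd,
         income_year_sd = income_year_sd,
         sick_prob_mean = sick_prob_mean,
         sick_prob_concentration = sick_prob_concentration,
         sick_income_drop = sick_income_drop,
         true_params = true_params,
         noise_sd = noise_sd,
         round_outcome = isTRUE(round_outcome),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Simulate a person-year panel
#'
#' Draws a panel whose life satisfaction equals the state-dependent HARA
#' prediction at each record's income, sickness state and controls under
#' `config$true_params`, plus Gaussian noise, optionally rounded and
#' clipped to the survey's integer 0-10 scale. Deterministic given
#' `config$seed`.
#'
#' Controls (age, household size, female, married) are generated
#' independently of income and sickness; their coefficients in the
#' outcome are `true_params$tau` (zero when `tau` is empty). Sampling
#' weights are mean-one lognormal draws.
#'
#' Errors rather than silently truncating: generation fails if any
#' record violates the utility domain `y - omega - theta*S > 0`, or if
#' (with `round_outcome = FALSE`) any noise-free prediction falls
#' outside `[0, 10]`.
#'
#' @param config A [synthetic_config()] object.
#' @return A data frame with columns `person_id`, `year`, `net_income`
#'   (thousand EUR/yr), `sick`, `life_satisfaction`, `age`,
#'   `household_size`, `female`, `married`, `weight`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  len <- pmax(2L, stats::rpois(n, config$years_per_individual))
  rows <- sum(len)
  id <- rep.int(seq_len(n), len)

  p_sick <- if (config$sick_prob_mean == 0) {
    rep(0, n)
  } else if (config$sick_prob_mean == 1) {
    rep(1, n)
  } else {
    stats::rbeta(n,
                 config$sick_prob_mean * config$sick_prob_concentration,
                 (1 - config$sick_prob_mean) * config$sick_prob_concentration)
  }
  sick <- stats::rbinom(rows, 1L, rep.int(p_sick, len))

  base_income <- rep.int(
    stats::rlnorm(n, config$income_log_mean, config$income_log_sd), len)
  shock <- stats::rlnorm(rows, -config$income_year_sd^2 / 2,
                         config$income_year_sd)
  healthy_income <- base_income * shock
  net_income <- healthy_income * (1 - config$sick_income_drop * sick)

  # calendar years inside 1993-2018; panels longer than the window are
  # left-anchored
  start_lo <- 1993L
  start_hi <- pmax(start_lo, 2018L - len + 1L)
  start <- start_lo + floor(stats::runif(n) * (start_hi - start_lo + 1L))
  year <- rep.int(start, len) + sequence(len) - 1L

  age0 <- 19L + floor(stats::runif(n) * pmax(1L, 64L - len - 18L))
  age <- rep.int(age0, len) + sequence(len) - 1L
  household_size <- rep.int(1L + stats::rbinom(n, 5L, 0.3), len)
  female <- rep.int(stats::rbinom(n, 1L, 0.5), len)
  married <- rep.int(stats::rbinom(n, 1L, 0.6), len)
  weight <- stats::rlnorm(rows, -0.045, 0.3)

  panel <- data.frame(
    person_id = id, year = year, net_income = net_income, sick = sick,
    life_satisfaction = NA_real_, age = age,
    household_size = household_size, female = female, married = married,
    weight = weight
  )

  z <- panel$net_income - config$true_params$omega -
    config$true_params$theta * panel$sick
  if (any(z <= 0)) {
    bad <- which(z <= 0)[1L]
    stop(sprintf(
      "incompatible config: utility domain violated at person %d, year %d (net_income = %.4g, sick = %d)",
      panel$person_id[bad], panel$year[bad], panel$net_income[bad],
      panel$sick[bad]
    ))
  }
  mu <- evaluate_utility(panel$net_income, panel$sick, config$true_params,
                         controls_effect(panel, config$true_params))
  ls <- mu + if (config$noise_sd > 0) stats::rnorm(rows, 0, config$noise_sd) else 0
  if (config$round_outcome) {
    ls <- pmin(10, pmax(0, round(ls)))
  } else if (any(mu < 0 | mu > 10)) {
    bad <- which(mu < 0 | mu > 10)[1L]
    stop(sprintf(
      "incompatible config: noise-free prediction %.3g outside [0, 10] at person %d, year %d",
      mu[bad], panel$person_id[bad], panel$year[bad]
    ))
  }
  panel$life_satisfaction <- ls
  panel
}

#' Keep only individuals observed in both sickness states
#'
#' Retains every person-year of each individual who has at least one
#' sick and at least one healthy year ("switchers"), on whose
#' within-person state changes identification of the fixed cost of
#' sickness rests. Idempotent. An empty result triggers a warning and is
#' returned as an empty panel.
#'
#' @param panel A panel data frame.
#' @return The panel restricted to switchers.
#' @export
filter_switchers <- function(panel) {
  validate_panel(panel, need_ls = FALSE)
  n_sick <- stats::ave(panel$sick, panel$person_id, FUN = sum)
  n_obs <- stats::ave(panel$sick, panel$person_id, FUN = length)
  out <- panel[n_sick >= 1 & n_sick < n_obs, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("no switchers in panel; returning empty panel")
  }
  rownames(out) <- NULL
  out
}

#' Descriptive statistics by sickness state
#'
#' The descriptive-table analog for a panel: weighted and unweighted
#' mean/SD of life satisfaction and net income by state, person-year
#' counts, the number of individuals, and mean (sick) periods per
#' individual.
#'
#' @param panel A nonempty panel data frame.
#' @return A list with elements `by_state` (data frame, one row per
#'   state), `n_individuals`, `mean_periods`, `mean_sick_periods`,
#'   `ls_gap` (healthy-minus-sick unweighted mean life satisfaction) and
#'   `income_gap` (proportional healthy-vs-sick mean income difference).
#' @export
summarize_panel <- function(panel) {
  validate_panel(panel)
  if (nrow(panel) == 0L) stop("panel is empty")
  one_state <- function(s) {
    sub <- panel[panel$sick == s, , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(data.frame(state = ifelse(s == 1, "sick", "healthy"), n = 0L,
                        ls_mean = NA_real_, ls_sd = NA_real_,
                        income_mean = NA_real_, income_sd = NA_real_,
                        ls_mean_w = NA_real_, income_mean_w = NA_real_))
    }
    data.frame(
      state = ifelse(s == 1, "sick", "healthy"),
      n = nrow(sub),
      ls_mean = mean(sub$life_satisfaction),
      ls_sd = stats::sd(sub$life_satisfaction),
      income_mean = mean(sub$net_income),
      income_sd = stats::sd(sub$net_income),
      ls_mean_w = stats::weighted.mean(sub$life_satisfaction, sub$weight),
      income_mean_w = stats::weighted.mean(sub$net_income, sub$weight)
    )
  }
  by_state <- rbind(one_state(0), one_state(1))
  periods <- tapply(panel$sick, panel$person_id, length)
  sick_periods <- tapply(panel$sick, panel$person_id, sum)
  list(
    by_state = by_state,
    n_individuals = length(periods),
    mean_periods = mean(periods),
    mean_sick_periods = mean(sick_periods),
    ls_gap = by_state$ls_mean[1L] - by_state$ls_mean[2L],
    income_gap = 1 - by_state$income_mean[2L] / by_state$income_mean[1L]
  )
}

#' @noRd
panel_columns <- c("person_id", "year", "net_income", "sick",
                   "life_satisfaction", "age", "household_size", "female",
                   "married", "weight")

#' @keywords internal
#' @noRd
validate_panel <- function(panel, need_ls = TRUE) {
  if (!is.data.frame(panel)) stop("panel must be a data frame")
  need <- setdiff(panel_columns, if (need_ls) character(0) else "life_satisfaction")
  missing <- setdiff(need, names(panel))
  if (length(missing)) {
    stop("panel is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(panel) > 0L) {
    if (any(panel$net_income <= 0)) stop("net_income must be positive")
    if (any(panel$weight <= 0)) stop("weights must be positive")
    if (!all(panel$sick %in% c(0, 1))) stop("sick must be 0/1")
  }
  invisible(panel)
}

#' Write a panel to CSV
#'
#' Fixed, documented column set; plain `write.csv` without row names so
#' panels round-trip through [read_panel()].
#'
#' @param panel A panel data frame.
#' @param path Output file path.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  utils::write.csv(panel[, panel_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read a panel from CSV
#'
#' @param path CSV file written by [write_panel()] (or any file with the
#'   same column set).
#' @return A validated panel data frame.
#' @export
read_panel <- function(path) {
  panel <- utils::read.csv(path)
  validate_panel(panel)
  panel
}
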