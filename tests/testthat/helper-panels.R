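# shared fixture builders; everything is generated in code at test time

# a small calibrated panel; defaults keep unit tests fast
small_panel <- function(n_ind = 300, seed = 7, noise_sd = 0.5,
                        params = hara_reference_params("main"), ...) {
  simulate_panel(synthetic_config(n_individuals = n_ind, seed = seed,
                                  noise_sd = noise_sd, true_params = params,
                                  ...))
}

# hand-built panel rows with sensible control defaults
toy_panel <- function(person_id, net_income, sick, life_satisfaction,
                      year = NULL, weight = 1) {
  n <- length(person_id)
  if (is.null(year)) {
    year <- stats::ave(rep(0L, n), person_id, FUN = seq_along) + 1999L
  }
  data.frame(
    person_id = person_id, year = year, net_income = net_income,
    sick = sick, life_satisfaction = life_satisfaction,
    age = 40L, household_size = 2L, female = 0L, married = 1L,
    weight = rep_len(weight, n)
  )
}

# random valid parameter sets for property-style loops (negative shifts,
# so the whole positive income axis is in-domain)
random_valid_params <- function(k, seed = 1) {
  set.seed(seed)
  lapply(seq_len(k), function(i) {
    utility_params(
      alpha = stats::runif(1, 5, 12),
      beta = stats::runif(1, 200, 5000),
      gamma = stats::runif(1, 1.2, 4.5),
      omega = stats::runif(1, -90, -20),
      theta = stats::runif(1, -5, 10),
      delta = stats::runif(1, -0.5, 0.1)
    )
  })
}

# high-order central-difference stencils: the independent oracle for the
# closed-form derivative checks
num_d1 <- function(f, x, h) {
  (-f(x + 2 * h) + 8 * f(x + h) - 8 * f(x - h) + f(x - 2 * h)) / (12 * h)
}
num_d2 <- function(f, x, h) {
  (-f(x + 2 * h) + 16 * f(x + h) - 30 * f(x) + 16 * f(x - h) -
     f(x - 2 * h)) / (12 * h^2)
}
num_d3 <- function(f, x, h) {
  (-f(x + 3 * h) + 8 * f(x + 2 * h) - 13 * f(x + h) + 13 * f(x - h) -
     8 * f(x - 2 * h) + f(x - 3 * h)) / (8 * h^3)
}
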