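# sickinsure

State-dependent utility estimation and optimal sickness insurance in R.

## What it is for

How valuable is a euro of sickness benefit to someone on long sickness
absence, compared with the same person in a healthy year? `sickinsure`
answers this with the income–well-being gradient: it fits a
state-dependent HARA utility function to person-year panels of net
income, a more-than-six-weeks sickness-absence indicator and 0–10 life
satisfaction (the structure of German Socio-Economic Panel style
surveys), and maps the estimates into Baily–Chetty-type optimal
replacement-rate schedules. It is aimed at health and public economists
working on social-insurance design, and at anyone who needs a tested
reference implementation of the method — including a calibrated
synthetic-panel generator, since the survey microdata themselves are
restricted-access.

The estimating equation is

```
LS_i = alpha + beta/(1-gamma) * ((y_i - omega - theta*S_i)/gamma)^(1-gamma)
       + delta*S_i + tau'X_i + eps_i
```

with income `y` in thousand EUR/yr and `S` the sick-year indicator:
`theta` is the *fixed cost of sickness* (a horizontal shift of the
utility curve in the sick state; `theta > 0` means higher marginal
utility when sick), `omega` the *institutions* parameter (a common
horizontal shift; negative values make relative risk aversion
`gamma*y/(y - omega - theta*S)` increase with income), and `delta` a
level effect that does not touch marginal utility. The fit is weighted
nonlinear least squares (Levenberg–Marquardt) with multi-start selection
across the curvature regimes separated by the non-smooth `gamma = 1`
boundary. The optimal replacement rate at healthy income `ye`, given a
moral-hazard elasticity sum `eps`, is the closed form

```
RR(ye) = omega/ye + theta/ye + (1 - omega/ye) * (1 + eps)^(-1/gamma).
```

Benchmark specifications — a loglinear individual-fixed-effects
regression with a log-income-by-sickness interaction, and penalized
cubic splines of the gradient by state — are included for cross-model
comparison.

## Worked example

Simulate a calibrated panel, keep the switchers, fit the utility model
and compute the policy schedule:

```r
library(sickinsure)

cfg   <- synthetic_config(seed = 42)          # calibrated default design
panel <- filter_switchers(simulate_panel(cfg))
summarize_panel(panel)$by_state
#>    state     n ls_mean income_mean income_sd
#>  healthy 56387    9.19       47.38     28.68
#>     sick 11171    8.84       45.49     27.46

fit <- multi_start_fit(panel, use_controls = FALSE)
fit
#> State-dependent HARA utility fit (power branch) [regime: default]
#>                estimate        se sig
#> alpha            9.8789    0.0925 ***
#> beta (printed) 232.9278 2092.2224
#> gamma            4.3714    2.4389 *
#> omega          -94.1969   76.5395
#> theta            3.9055    1.3078 ***
#> delta           -0.2481    0.0321 ***
#> n = 67558, SSE = 1.73e+05, residual SE = 1.6, converged = TRUE (429 iterations)

optimal_replacement_rate(47.42665, 1.5, fit$params)
#> [1] 0.5180218

curve <- policy_curve(policy_config(fit$params, 1.5, seq(20, 80, 20)))
curve[, c("income", "optimal_rr", "rr_theta0")]
#>  income optimal_rr rr_theta0
#>      20      0.116    -0.080
#>      40      0.463     0.366
#>      60      0.579     0.514
#>      80      0.637     0.588
```

Reading the output: the panel was generated with a fixed cost of
sickness of 4.86 thousand EUR/yr; the fit recovers `theta` within one
standard error (3.91 ± 1.31) and it is the stable, strongly significant
parameter. The curvature `gamma` sits on a flat ridge (note its standard
error) — that weak identification is a property of the model on this
kind of data, and the honest standard errors carry it. The schedule
rises with income because the negative `omega` gives low incomes a
consumption floor, and the `rr_theta0` column shows what insurance would
look like without the fixed cost: `theta` adds exactly `theta/income`,
so it matters most at the bottom. At the sample mean income the optimal
replacement rate lands between the 0.5 and 0.7 replacement rates of
well-known European sickness-insurance schemes.

The benchmarks work the same way:

```r
fit_loglinear_fe(panel, controls = FALSE)   # FE regression; interaction ~ sign(theta)
spline_gradient(panel, state = 0)           # nonparametric gradient, healthy years
```

A thin command-line wrapper over these functions is installed at
`inst/cli/sickinsure.R` (subcommands `simulate`, `fit`, `policy`).

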