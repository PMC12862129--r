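Package: sickinsure
Title: State-Dependent Utility Estimation and Optimal Sickness Insurance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a state-dependent HARA utility function with a fixed
    cost of sickness from person-year panels of net income, sickness-absence
    status and 0-10 life satisfaction, by weighted nonlinear least squares
    with multi-start curvature-regime selection. Maps the estimates into
    Baily-Chetty-type optimal sickness-insurance replacement-rate schedules,
    and provides loglinear fixed-effects and penalized-spline benchmark
    specifications. Includes a calibrated generator of SOEP-like "switcher"
    panels so the full pipeline is testable without restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    mgcv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
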