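Package: eldercast
Title: Health-State Transitions and Medical Expenditure Forecasting for
    Elderly Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the self-rated health dynamics of elderly
    survey cohorts and forecasting their medical expenditure. Estimates a
    five-state (four living self-rated health states plus absorbing death)
    discrete-time transition probability matrix from two-wave panel data via
    multinomial logistic regression, fits a two-part (probit participation
    plus linear level) model of medical expenditure, projects the population
    by health state with Chapman-Kolmogorov matrix powers including cohort
    aging and exogenous new entrants, and aggregates projected populations
    with per-capita expenditures into total expenditure forecasts. Includes a
    synthetic panel generator with known ground truth for validation, and
    bundled published transition and expenditure tables for reproduction of
    the downstream arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
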