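Package: hwle
Title: Healthy Working Life Expectancy from Interval-Censored Panel Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of healthy working life expectancy (HWLE) and related
    health expectancies from irregularly spaced longitudinal survey panels
    with linked mortality. Implements an interpolated Markov chain multi-state
    model over four alive health/work states plus death: one-step transition
    probabilities are multinomial logits in age and covariates, chained into
    interval transition matrices and fitted by maximum likelihood to
    interval-censored transitions. Fitted models yield state expectancies by
    starting state, prevalence-weighted population expectancies (HWLE and
    total life expectancy), age curves, and simulation-based confidence
    intervals. Includes a period life-table estimator as an independent
    mortality cross-check and a synthetic cohort generator emulating the
    structure of ageing-survey panels (wave schedules, refreshment samples,
    attrition, missing states, month-precision death ages).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet
Config/testthat/edition: 3
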