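---
title: "Estimating healthy working life expectancy from panel data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating healthy working life expectancy from panel data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hwle)
```

## The estimation problem

Ageing surveys interview people every few years, classify them at each
interview into one of four alive states — healthy and in paid work (state 1),
healthy and not working (2), not healthy and working (3), not healthy and not
working (4) — and link deaths from a mortality register. Healthy working life
expectancy (HWLE) at an index age is the expected number of remaining years
spent simultaneously healthy and in work. The estimation difficulty is that
the state is observed only at irregular interview dates: transitions between
interviews are interval-censored, people enter the panel at different ages
(refreshment samples), drop out, and sometimes answer enough questions to be
known alive but not enough to classify their state.

`hwle` addresses this with an interpolated Markov chain multi-state model.
Time is cut into short interpolation steps (12 months by default, optionally
1 month). Over one step the transition probabilities out of each live origin
state follow a multinomial logit with "stay in the origin state" as the
reference outcome:

$$
P(o \to d) = \frac{\exp(\eta_{od})}{1 + \sum_{d'} \exp(\eta_{od'})},
\qquad
\eta_{od} = \beta_{od,0} + \beta_{od,\mathrm{age}}\,(a - 50) + \sum_k \beta_{od,k}\,x_k,
$$

with death absorbing. An observed transition spanning several steps has
probability equal to the corresponding ordered product of step matrices, so
the likelihood of a trajectory is the product over its observation pairs —
the Markov property makes the pairs conditionally independent given the
states at their origins.

## Likelihood contributions

Each consecutive observation pair contributes one record:

* a **live** destination contributes the `[origin, destination]` entry of the
  interval matrix;
* a destination observed alive but with **unknown state** (health or work item
  missing) contributes the probability of being in *any* live state — it
  informs survival but not movement, and observations with incomplete
  covariates are excluded record-by-record;
* a linked **death** contributes the probability of surviving to the step
  that contains the month-precision death age and dying within it,
  $M_n[o,\mathrm{dead}] - M_{n-1}[o,\mathrm{dead}]$. We deliberately use this
  difference form rather than the cumulative dead entry: the cumulative form
  asserts only "dead by age $x$", discards the known death interval, and
  biases mortality when origins and deaths are offset within the year;
* a subject alive at the mortality-linkage end contributes a terminal
  survival-only record from the last interview to `followup_end_age`.

The last rule deserves emphasis. Register linkage determines vital status for
*every* subject up to the linkage end, including people who stopped answering
interviews. If deaths after dropout are kept (they are in the register) while
surviving dropouts are censored at their last interview, the likelihood sees
deaths with no matching survivor exposure and overstates mortality — with a
ten-year linkage window and realistic attrition the distortion is of the
order of years of life expectancy, not a rounding effect. The
default therefore extends survivors to the linkage end
(`survivors = "linkage_end"` in `extract_transitions()`, `fit_mle()` and
`build_lifetable()`); censoring at the last interview remains available for
sensitivity analysis.

Records whose origin state is unknown (state 0) cannot be conditioned on and
are dropped with a logged count; because state missingness is a few per cent
and unrelated to the process, this loses a little information but introduces
no bias of consequence.

## The age term and the interpolation grid

Interpolation steps run from each subject's own observation ages, which are
spread across the year. The age entering $\eta$ for a step is, by default,
the **integer age nearest the step start** (`age_term = "nearest"`). Two
alternatives are provided:

* `"floor"` — the integer age at the step start, making probabilities
  constant within each calendar year of age. This is the convention suggested
  by descriptions of interpolated-Markov-chain software. It has a subtle
  population-level consequence: a subject whose grid is offset by $f$ of a
  year has every hazard evaluated $f$ years too young, and since entry months
  are spread across the year ($E[f] \approx 0.46$ on the month grid) the
  population's measured mortality lags its true age by almost half a year.
  The lag is invisible to parameter recovery (the likelihood uses the same
  convention as the data) but it drives a wedge of about $E[f]$ years between
  the expectancy module's LE, projected from an exact integer starting age,
  and the period life table, which averages over the offsets — a structural
  disagreement that no sample size removes.
* `"exact"` — the fractional age at the step start; statistically clean but
  it defeats the integer-age caching that keeps large fits fast.

`"nearest"` keeps integer ages (probabilities constant within half-shifted
year-of-age bands, and fast caching) while the grid offsets cancel exactly in
expectation: conditional on true age-year $x$, the average evaluation age is
$f(x-1) + (1-f)x$ for $f < \tfrac12$ and $fx + (1-f)(x+1)$ otherwise, which
integrates to exactly $x$ over $f \sim U(0,1)$. The acceptance checks verify
the consequence: multistate and life-table LE from the same 10,000-subject
panel agree to a few hundredths of a year under `nearest`.

Fractional observation ages are snapped to a whole number of steps (nearest,
ties to even); month-precision death ages map to the step containing the
death month (`death_snap = "floor"`, with `"round"` as the alternative).

## Estimation and uncertainty

`fit_mle()` maximises the log-likelihood with a bounded quasi-Newton search
(`optim` L-BFGS-B; coefficients bounded in [-30, 30] on the optimiser scale,
age scaled to decades internally for conditioning and reported per year).
Starting intercepts come from crude per-cell event rates, which roughly
halves the iteration count. Admissible cells with no observed events are not
estimable; they are frozen at intercept -30 (step probability effectively 0)
with a message — the situation arises in small strata, e.g. rare transitions
among people with a particular covariate combination. Convergence is declared
by the optimiser's relative-improvement criterion; the achieved gradient norm
is reported in `diagnostics` rather than hard-thresholded, because
finite-difference gradients on a log-likelihood of magnitude $10^3$–$10^4$
carry numerical noise well above any fixed tiny tolerance.

The coefficient covariance is the inverse of the numerically differentiated
observed information; if that matrix is singular (typically when a frozen or
near-frozen cell leaves a flat direction) a pseudo-inverse is used with a
warning. Confidence intervals for expectancies are obtained by parametric
simulation: draw coefficient vectors from the fitted normal approximation,
recompute the expectancies per draw, and take the 2.5/97.5 percentiles
(`n_draws = 1000` by default, seed recorded). The observed prevalence weights
are held fixed across draws; their multinomial error is small relative to
coefficient uncertainty at survey sample sizes, and the recovery checks add
it explicitly where it matters. A delta-method alternative was considered
and rejected for the package default because the simulation route makes no
linearity assumption and is directly verifiable.

## From transition model to expectancies

`occupancy_profile()` projects a starting indicator forward through the step
matrices; `state_expectancies()` accumulates occupancy by the trapezoid rule
(half credit for the boundary steps),

$$
e_{ij} = \frac{h}{12} \sum_t \frac{p_{ij}(t) + p_{ij}(t+1)}{2},
$$

up to the closure age (110 by default: the oldest respondents in the surveys
this emulates were observed at 98–102, and residual live mass above 110 is
negligible under any fitted hazard; `integration = "left"` is exposed for
sensitivity). For a time-homogeneous chain this sum has the closed form
$(I-Q)^{-1} - I/2$ in the live-state block, which the tests use as an
independent oracle. Population values weight the rows of $e$ by the observed
state prevalence at the index age (`observed_prevalence()`: first observation
per subject within a ±2.5-year window, unknown states excluded — the
de-duplication avoids over-representing frequent responders). HWLE is the
weighted expectancy of state 1 and total LE is the sum of the four weighted
expectancies, an identity that holds exactly by construction and is asserted
on every run.

## The period life table

`build_lifetable()` estimates mortality from the same panel without using the
health/work classification: person-years of exposure from first observation
to death or linkage end, deaths at the single year of age containing the
death month, $m_x = D_x/\mathrm{PY}_x$, $q_x = m_x/(1 + 0.5\,m_x)$
($a_x = 0.5$ throughout — no infant correction is needed above 50), radix
100,000, and the final open interval closed with $e_\omega = 1/m_\omega$.
Ages with no exposure borrow $q_x$ from the nearest estimated age, with a
warning. The resulting $e_{50}$ is the package's independent mortality
cross-check: the multistate LE and the life-table LE are estimated from the
same data by unrelated routes, and their agreement (within half a year on a
10,000-subject simulation) is the package's analogue of comparing summed
health expectancies against life-table life expectancy. The open-interval
closure assumes a constant hazard beyond $\omega$, which is innocuous only
when survivorship to $\omega$ is small — one reason the synthetic cohorts
recruit across the full 50–90 entry range (below).

## What the synthetic cohorts emulate

`generate_cohort()` produces panels with the structure the estimator assumes,
plus a truth record for recovery studies. Two presets:

* `elsa_like`: six waves two years apart, refreshment entry at waves 3/4/6
  (30% of subjects), occupation unmeasured at wave 1, time-dependent
  osteoarthritis (prevalence 0.25 at 50, onset hazard 0.02/year thereafter,
  irreversible), covariate missingness 3%, mortality linkage 10 years.
* `norstop_like`: baseline plus 3- and 6-year follow-ups, a fixed
  osteoarthritis flag (probability 0.3) as from medical-record consultation,
  linkage 6 years.

Shared defaults, chosen once from the cohort descriptions the presets
emulate: entry ages uniform on the month grid over 50–90 (the surveys recruit
adults aged 50 and over; the oldest observed ages were 98–102, and a narrower
entry range would leave the life table's open interval carrying substantial
survivorship), sex Bernoulli(0.5), occupation (self-employed 0.1, non-manual
0.5, manual 0.4), state distribution at age 50 of (0.55, 0.23, 0.08, 0.14),
attrition 0.10 per wave, state missingness 0.05. The generating coefficients
(in `inst/extdata/beta_true_default.csv`) are calibrated so population HWLE
at 50 is ≈7 years and LE ≈31 years — the magnitudes published for England —
with osteoarthritis reducing HWLE by about a third.

The latent path evolves on the generating model's own step grid, aligned to
each subject's fractional entry age, by sampling successive rows of
`step_matrix()` — the same function the likelihood uses, so generation and
estimation are mutually consistent by construction. Subjects are conditioned
on being alive at entry (rejection sampling), as a real panel only recruits
survivors; deaths get a month-precision age inside the fatal step; one master
seed spawns per-subject seeds so cohorts are reproducible and independent of
subject order.

What the generator does *not* emulate — and hence what passing recovery tests
cannot certify about real data: sampling weights and household clustering,
state-dependent attrition and item missingness (both are independent of the
path here, so censoring is non-informative by construction), recall error in
interview answers, calendar-period effects, and any non-Markov dependence on
state history. On real panels those features bias in ways no internal check
can detect.

## Analysis designs and problem sizes

Time-dependent covariates enter the transition model as covariates
(`mode = "covariate"` in `run_config()`, covariate value taken at each
record's origin); fixed group labels can instead stratify the data into
independent fits (`mode = "stratified"`), which is saturated-equivalent to a
fully interacted covariate model — a property the tests verify on a fixed
binary flag. `run_analysis()` chains simulation (or reading), fitting,
expectancy tables at the index ages (50 and 65 by default), the HWLE-by-age
curve over 50–75, percent-of-LE summaries, the life-table cross-check and a
run log; `consistency_check()` asserts sum-to-LE (tolerance 0.005 years
before rounding — rounding to two decimals happens only at the serialisation
boundary), HWLE ≤ LE, and CI coverage of point estimates.

The shipped verification studies use cohorts of 250–10,000 subjects: 5,000
for expectancy recovery (matching the scale at which the Monte-Carlo error of
fitted HWLE is a few tenths of a year), 10,000 for the lifetable comparison,
50 replicates of 250 for Wald coverage, and 2,000 for the yearly-vs-monthly
step comparison. These sizes give each check adequate power while keeping a
full verification run in the tens of minutes on one core.

## Known limitations

* Occupation in ELSA-like designs is first measured at wave 2, so wave-1-only
  decedents never have an occupation: analyses by occupation type carry a
  survivorship bias that the package documents but does not correct, and
  percent-of-LE by occupation should not be interpreted causally.
* Records whose origin state is unknown are dropped rather than marginalised
  over origin states.
* The model is a discrete-step chain, not a continuous-time intensity model;
  covariate values are held at their origin-observation value across an
  interval, which attenuates effects of covariates that switch mid-interval
  (osteoarthritis onset is slow, so the attenuation is small).
* Expectancies are period quantities under the fitted age profile; no cohort
  projection or incidence/mortality decomposition is attempted.
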