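# exact truncated closed form for a time-homogeneous chain with live block Q:
# E = w * (S_n - (I - Q^n)/2),  S_n = (I-Q)^{-1} (I - Q^n),  w = h/12
trunc_fundamental_oracle <- function(Q, n, w) {
  Qn <- diag(4)
  for (i in seq_len(n)) Qn <- Qn %*% Q
  Sn <- solve(diag(4) - Q) %*% (diag(4) - Qn)
  w * (Sn - (diag(4) - Qn) / 2)
}

test_that("occupancy stays put under a frozen chain and dies under an absorbing one", {
  spec <- model_spec(terms = "intercept")
  frozen <- coef_template(spec, value = -30)
  P <- occupancy_profile(list(beta = frozen, spec = spec), NULL, 50, 2)
  expect_true(all(abs(P[, 2] - 1) < 1e-9))

  killer <- coef_template(spec, value = -30)
  killer[, 5, 1] <- 30
  P2 <- occupancy_profile(list(beta = killer, spec = spec), NULL, 50, 1)
  expect_true(all(rowSums(P2[-1, 1:4, drop = FALSE]) < 1e-9))

  # immediate death leaves only the initial half step of occupancy credit
  E <- state_expectancies(list(beta = killer, spec = spec), NULL, 50)
  expect_equal(unname(diag(E)), rep(12 / 24, 4), tolerance = 1e-9)
  expect_true(all(E[row(E) != col(E)] < 1e-9))
})

test_that("occupancy of a time-homogeneous chain equals the matrix power", {
  spec <- model_spec(terms = "intercept")
  b <- random_homogeneous_beta(spec, seed = 5)
  S <- step_matrix(b, 60, NULL, spec)
  P <- occupancy_profile(list(beta = b, spec = spec), NULL, 60, 3)
  S5 <- diag(5); for (i in 1:5) S5 <- S5 %*% S
  expect_equal(unname(P[6, ]), unname((c(0, 0, 1, 0, 0) %*% S5)[1, ]), tolerance = 1e-12)
  # live mass is non-increasing
  expect_true(all(diff(rowSums(P[, 1:4])) <= 1e-15))
})

test_that("the two-state chain with q = 0.5 has expectancy 1.5 years", {
  spec <- two_state_spec()
  b <- two_state_beta(0.5)
  E <- state_expectancies(list(beta = b, spec = spec), NULL, 50)
  expect_equal(unname(E[1, 1]), 1.5, tolerance = 1e-9)
})

test_that("trapezoid expectancies match the fundamental-matrix closed form", {
  spec <- model_spec(terms = "intercept")
  for (seed in 1:5) {
    b <- random_homogeneous_beta(spec, seed = seed)
    S <- step_matrix(b, 60, NULL, spec)
    Q <- S[1:4, 1:4]
    E <- state_expectancies(list(beta = b, spec = spec), NULL, 50)
    n <- ceiling((spec$closure_age - 50) * 12 / spec$step_months)
    expect_equal(unname(E), unname(trunc_fundamental_oracle(Q, n, 1)), tolerance = 1e-9)
    # heavy mortality: truncation is negligible, so the untruncated
    # fundamental matrix agrees too
    expect_equal(unname(E), unname(solve(diag(4) - Q) - diag(4) / 2), tolerance = 1e-6)
  }
})

test_that("left-endpoint integration exceeds trapezoid by the initial half step", {
  spec <- model_spec(terms = "intercept")
  b <- random_homogeneous_beta(spec, seed = 3)
  Et <- state_expectancies(list(beta = b, spec = spec), NULL, 50)
  El <- state_expectancies(list(beta = b, spec = spec), NULL, 50, integration = "left")
  expect_equal(unname(El - Et), unname(diag(4) / 2), tolerance = 1e-9)
})

test_that("observed prevalence counts known states in the window, one per subject", {
  pd <- make_panel(list(c(1L, 1L), 1L, 4L, 4L, 0L),
                   list(c(50.5, 51.5), 49, 51, 52, 50))
  pr <- observed_prevalence(pd, 50, window = 5)
  # subjects 1 (first obs 50.5), 2 (49), 3 (51), 4 (52): two in state 1, two in 4;
  # state-0 subject 5 excluded; subject 1's second observation not double-counted
  expect_identical(pr$n, 4L)
  expect_equal(unname(pr$pi), c(0.5, 0, 0, 0.5))

  pd1 <- make_panel(list(1L, 1L), list(50, 51))
  pr1 <- observed_prevalence(pd1, 50.5, window = 2)
  expect_equal(unname(pr1$pi), c(1, 0, 0, 0))

  expect_error(observed_prevalence(pd, 90, window = 2), "widen the window")
})

test_that("prevalence weighting reproduces hand arithmetic", {
  e <- matrix(0, 4, 4)
  e[1, ] <- c(10, 2, 1, 3)
  e[2, ] <- c(6, 5, 2, 4)
  w <- weighted_expectancies(e, c(0.25, 0.75, 0, 0))
  expect_equal(unname(w$weighted), c(0.25 * 10 + 0.75 * 6, 0.25 * 2 + 0.75 * 5,
                                     0.25 * 1 + 0.75 * 2, 0.25 * 3 + 0.75 * 4))
  expect_equal(w$le, sum(w$weighted))

  # point mass picks out a row; identical rows make the weights irrelevant
  w1 <- weighted_expectancies(e, c(1, 0, 0, 0))
  expect_equal(unname(w1$weighted), e[1, ])
  eq <- matrix(rep(c(4, 3, 2, 1), each = 4), 4, 4)
  expect_equal(weighted_expectancies(eq, c(0.1, 0.2, 0.3, 0.4))$weighted,
               weighted_expectancies(eq, c(1, 0, 0, 0))$weighted)

  expect_error(weighted_expectancies(e, c(0.5, 0.4, 0, 0)), "sum to 1")
})

# one small fitted model shared by the CI tests
local({
  spec <- two_state_spec()
  set.seed(14)
  dest <- rbinom(400, 1, 0.2)
  recs <- make_records(data.frame(
    origin_state = 1L, origin_age = 50,
    dest_kind = ifelse(dest == 1, "dead", "live"),
    dest_state = ifelse(dest == 1, NA_integer_, 1L),
    dest_age = ifelse(dest == 1, 50.5, 51)))
  fit <- suppressMessages(fit_mle(recs, spec))
  pi1 <- c(1, 0, 0, 0)

  test_that("zero covariance collapses the interval onto the point estimate", {
    fit0 <- fit
    fit0$vcov[] <- 0
    ci <- expectancy_ci(fit0, NULL, 50, pi1, n_draws = 50, seed = 2)
    expect_equal(ci$lower, ci$estimate, tolerance = 1e-9)
    expect_equal(ci$upper, ci$estimate, tolerance = 1e-9)
  })

  test_that("doubling the covariance widens every interval at a fixed seed", {
    ci1 <- expectancy_ci(fit, NULL, 50, pi1, n_draws = 400, seed = 2)
    fit2 <- fit
    fit2$vcov <- fit$vcov * 4
    ci2 <- expectancy_ci(fit2, NULL, 50, pi1, n_draws = 400, seed = 2)
    keep <- ci1$se > 0
    expect_true(all((ci2$upper - ci2$lower)[keep] > (ci1$upper - ci1$lower)[keep]))
  })

  test_that("interval draws are reproducible under a fixed seed", {
    ci1 <- expectancy_ci(fit, NULL, 50, pi1, n_draws = 100, seed = 5)
    ci2 <- expectancy_ci(fit, NULL, 50, pi1, n_draws = 100, seed = 5)
    expect_identical(ci1, ci2)
    ci3 <- expectancy_ci(fit, NULL, 50, pi1, n_draws = 100, seed = 6)
    expect_false(identical(ci1$lower, ci3$lower))
  })
})

test_that("expectancies vanish at the closure age", {
  spec <- model_spec(terms = "intercept")
  b <- random_homogeneous_beta(spec, seed = 8)
  E <- state_expectancies(list(beta = b, spec = spec), NULL, spec$closure_age)
  expect_true(all(E == 0))
})

test_that("the HWLE curve at an age agrees with the direct pipeline", {
  cfg <- sim_config("elsa_like", n_subjects = 250, seed = 17,
                    spec = model_spec(terms = "intercept"),
                    beta_true = local({
                      s <- model_spec(terms = "intercept")
                      b <- coef_template(s)
                      b[!is.na(b)] <- -2.5
                      b[, 5, 1] <- -3
                      b
                    }))
  gen <- generate_cohort(cfg)
  fit <- suppressMessages(fit_mle(gen$dataset, cfg$spec))
  crv <- hwle_curve(fit, gen$dataset, ages = c(55, 60))
  direct <- weighted_expectancies(state_expectancies(fit, NULL, 55),
                                  observed_prevalence(gen$dataset, 55))
  expect_equal(crv$hwle[crv$age == 55], unname(direct$weighted[1]), tolerance = 1e-12)
  expect_equal(crv$le[crv$age == 55], direct$le, tolerance = 1e-12)
})

test_that("percentage of life expectancy matches printed worked examples", {
  expect_identical(percent_of_le(5.68, 32.25), 17.6)
  expect_identical(percent_of_le(10.00, 31.31), 31.9)
  expect_identical(percent_of_le(0, 30), 0)
  expect_error(percent_of_le(5, 0), "positive")
})
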