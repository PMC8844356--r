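test_that("single-record contributions match interval-matrix entries", {
  spec <- model_spec(terms = "intercept")
  # origin-1 step row (stay, s2, s3, s4, dead) = (0.2, 0.3, 0.1, 0.2, 0.2)
  b <- coef_template(spec)
  b[1, 2, 1] <- log(0.3 / 0.2)
  b[1, 3, 1] <- log(0.1 / 0.2)
  b[1, 4, 1] <- log(0.2 / 0.2)
  b[1, 5, 1] <- log(0.2 / 0.2)
  b[2:4, , 1][!is.na(b[2:4, , 1])] <- -2

  rec_live <- list(origin_state = 1L, origin_age = 60, dest_kind = "live",
                   dest_state = 2L, dest_age = 61)
  P <- step_matrix(b, 60, NULL, spec)
  expect_equal(transition_loglik(b, rec_live, spec), log(P[1, 2]))
  expect_equal(P[1, 2], 0.3, tolerance = 1e-12)

  # survival-only record over one step: log of the live mass 1 - 0.2
  rec_unknown <- list(origin_state = 1L, origin_age = 60, dest_kind = "unknown",
                      dest_state = NA_integer_, dest_age = 61)
  expect_equal(transition_loglik(b, rec_unknown, spec), log(0.8), tolerance = 1e-12)

  # death inside the first step: log of the step's death probability
  rec_dead <- list(origin_state = 1L, origin_age = 60, dest_kind = "dead",
                   dest_state = NA_integer_, dest_age = 60.5)
  expect_equal(transition_loglik(b, rec_dead, spec), log(0.2), tolerance = 1e-12)

  expect_equal(transition_loglik(b, list(origin_state = 1L, dest_kind = "censored"), spec), 0)
  expect_error(transition_loglik(b, list(origin_state = 0L, dest_kind = "live"), spec),
               "origin state")
})

test_that("an observed transition forbidden by the mask is an error", {
  adj <- matrix(FALSE, 4, 5)
  adj[, 5] <- TRUE
  adj[1, 2] <- TRUE
  spec <- model_spec(terms = "intercept", adjacency = adj)
  b <- coef_template(spec, value = -1)
  rec <- list(origin_state = 3L, origin_age = 60, dest_kind = "live",
              dest_state = 1L, dest_age = 61)
  expect_error(transition_loglik(b, rec, spec), "zero probability")
})

test_that("the total log-likelihood is additive over records", {
  spec <- model_spec(terms = "intercept")
  set.seed(3)
  b <- coef_template(spec)
  b[!is.na(b)] <- rnorm(16, -2, 0.3)
  recs <- make_records(data.frame(
    origin_state = c(1L, 3L), origin_age = c(60, 70),
    dest_kind = "live", dest_state = c(2L, 3L), dest_age = c(61, 71)))
  ll <- total_loglik(b, recs, spec)
  singles <- sum(vapply(1:2, function(i) transition_loglik(b, recs[i, ], spec), numeric(1)))
  expect_equal(as.numeric(ll), singles, tolerance = 1e-12)
  expect_identical(attr(ll, "n_used"), 2L)
  doubled <- total_loglik(b, rbind(recs, recs), spec)
  expect_equal(as.numeric(doubled), 2 * singles, tolerance = 1e-12)
})

test_that("the two-state constant-hazard MLE equals the closed-form binomial logit", {
  spec <- two_state_spec()
  # 10 subjects at risk for one step: 3 deaths mid-step, 7 survivors
  recs <- make_records(data.frame(
    origin_state = 1L, origin_age = 50,
    dest_kind = rep(c("dead", "live"), c(3, 7)),
    dest_state = rep(c(NA_integer_, 1L), c(3, 7)),
    dest_age = rep(c(50.5, 51), c(3, 7))))
  fit <- fit_mle(recs, spec)
  expect_equal(fit$par$estimate[fit$par$origin == "s1"], qlogis(0.3), tolerance = 1e-4)
  # binomial information: se = 1/sqrt(n p (1-p))
  expect_equal(fit$par$std_error[fit$par$origin == "s1"],
               1 / sqrt(10 * 0.3 * 0.7), tolerance = 1e-2)
  expect_equal(fit$loglik, 3 * log(0.3) + 7 * log(0.7), tolerance = 1e-8)
})

test_that("single-step data reproduce the multinomial-logit fit from nnet", {
  skip_if_not_installed("nnet")
  spec <- model_spec(terms = "intercept")
  set.seed(11)
  b_true <- coef_template(spec)
  b_true[!is.na(b_true)] <- rnorm(16, -1.5, 0.4)
  recs <- list()
  for (o in 1:4) {
    P <- step_matrix(b_true, 60, NULL, spec)
    dest <- sample.int(5, 500, replace = TRUE, prob = P[o, ])
    recs[[o]] <- data.frame(
      origin_state = o, origin_age = 60,
      dest_kind = ifelse(dest == 5L, "dead", "live"),
      dest_state = ifelse(dest == 5L, NA_integer_, dest),
      dest_age = ifelse(dest == 5L, 60.5, 61))
  }
  recs <- make_records(do.call(rbind, recs))
  fit <- fit_mle(recs, spec)
  for (o in 1:4) {
    sub <- recs[recs$origin_state == o, ]
    y <- ifelse(sub$dest_kind == "dead", 5L, sub$dest_state)
    y <- stats::relevel(factor(y, levels = c(o, setdiff(1:5, o))), ref = as.character(o))
    mfit <- nnet::multinom(y ~ 1, trace = FALSE)
    ref <- setNames(as.numeric(coef(mfit)), rownames(coef(mfit)))
    ours <- fit$par[fit$par$origin == paste0("s", o), ]
    for (d in setdiff(1:5, o)) {
      lev <- as.character(d)
      if (!lev %in% names(ref)) next  # destination never sampled
      dn <- if (d == 5L) "dead" else paste0("s", d)
      expect_equal(ours$estimate[ours$destination == dn], ref[[lev]],
                   tolerance = 0.02)
    }
  }
})

test_that("the fit is invariant under record reordering", {
  spec <- model_spec(terms = "intercept")
  set.seed(21)
  b_true <- coef_template(spec)
  b_true[!is.na(b_true)] <- rnorm(16, -1.8, 0.3)
  P <- step_matrix(b_true, 60, NULL, spec)
  dest <- sample.int(5, 800, replace = TRUE, prob = P[1, ])
  recs <- make_records(data.frame(
    origin_state = 1L, origin_age = 60,
    dest_kind = ifelse(dest == 5L, "dead", "live"),
    dest_state = ifelse(dest == 5L, NA_integer_, dest),
    dest_age = ifelse(dest == 5L, 60.5, 61)))
  f1 <- fit_mle(recs, spec)
  f2 <- fit_mle(recs[sample(nrow(recs)), ], spec)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$par$estimate, f2$par$estimate, tolerance = 1e-6)
})

test_that("cells without observed events are frozen and the fit completes", {
  spec <- model_spec(terms = "intercept")
  # only 1->2 moves and 1->1 stays ever observed
  recs <- make_records(data.frame(
    origin_state = 1L, origin_age = 60,
    dest_kind = "live", dest_state = rep(c(2L, 1L), c(10, 30)),
    dest_age = 61))
  expect_message(fit <- fit_mle(recs, spec), "frozen")
  expect_equal(unname(unclass(fit$beta)[1, 3, 1]), -30)
  expect_equal(unname(unclass(fit$beta)[1, 5, 1]), -30)
  expect_identical(nrow(fit$par), 1L)
  expect_equal(fit$par$estimate[1], qlogis(0.25), tolerance = 1e-4)
})

test_that("the generating coefficients beat a perturbed set on large simulated data", {
  spec <- model_spec(terms = "intercept")
  set.seed(31)
  b_true <- coef_template(spec)
  b_true[!is.na(b_true)] <- rnorm(16, -2, 0.3)
  recs <- list()
  P <- step_matrix(b_true, 60, NULL, spec)
  for (o in 1:4) {
    dest <- sample.int(5, 1500, replace = TRUE, prob = P[o, ])
    recs[[o]] <- data.frame(
      origin_state = o, origin_age = 60,
      dest_kind = ifelse(dest == 5L, "dead", "live"),
      dest_state = ifelse(dest == 5L, NA_integer_, dest),
      dest_age = ifelse(dest == 5L, 60.5, 61))
  }
  recs <- make_records(do.call(rbind, recs))
  b_pert <- b_true
  b_pert[!is.na(b_pert)] <- b_pert[!is.na(b_pert)] + 0.5
  expect_gt(as.numeric(total_loglik(b_true, recs, spec)),
            as.numeric(total_loglik(b_pert, recs, spec)))
})

test_that("the likelihood at the optimum dominates the all-zero coefficients", {
  cfg <- sim_config("elsa_like", n_subjects = 120, seed = 8,
                    spec = model_spec(terms = "intercept"),
                    beta_true = local({
                      s <- model_spec(terms = "intercept")
                      b <- coef_template(s)
                      b[!is.na(b)] <- -2.5
                      b
                    }))
  gen <- generate_cohort(cfg)
  fit <- suppressMessages(fit_mle(gen$dataset, cfg$spec))
  b0 <- coef_template(cfg$spec, value = 0)
  expect_gt(fit$loglik, as.numeric(total_loglik(b0, gen$dataset, cfg$spec)))
})
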