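# accept either an hwle_fit or a list(beta, spec)
.beta_spec <- function(object) {
  if (inherits(object, "hwle_fit")) list(beta = object$beta, spec = object$spec)
  else if (is.list(object) && !is.null(object$beta) && !is.null(object$spec)) object
  else stop("object must be an hwle_fit or a list(beta = , spec = )")
}

#' State occupancy probabilities from a starting state
#'
#' Forward projection `p(t+1) = p(t) %*% S(age_t)` from an indicator at the
#' starting age up to the closure age. Live-state mass is non-increasing in t.
#'
#' @param object an `hwle_fit` or `list(beta, spec)`.
#' @param profile named covariate values held fixed over the projection.
#' @param start_age starting age in years.
#' @param start_state starting live state (1-4).
#' @return (n_steps + 1) x 5 matrix of occupancy probabilities with an
#'   `ages` attribute.
#' @export
occupancy_profile <- function(object, profile = NULL, start_age = 50, start_state = 1) {
  bs <- .beta_spec(object)
  stopifnot(start_state %in% 1:4)
  spec <- bs$spec
  h <- spec$step_months
  m0 <- as.integer(round(start_age * 12))
  n <- ceiling((spec$closure_age * 12 - m0) / h)
  cache <- .tm_cache(bs$beta, spec, profile)
  P <- matrix(0, n + 1L, 5, dimnames = list(NULL, .STATE_NAMES))
  P[1, start_state] <- 1
  for (t in seq_len(n)) {
    P[t + 1L, ] <- P[t, ] %*% cache$getS(.age_key(m0 + h * (t - 1L), spec))
  }
  attr(P, "ages") <- (m0 + h * (0:n)) / 12
  P
}

#' Expected years in each live state by starting state
#'
#' `e[i, j]` is the expected number of years spent in live state `j` from
#' `start_age` up to the closure age, given occupancy of state `i` at
#' `start_age`. Occupancy is accumulated by the trapezoid rule over
#' interpolation steps (half credit for the boundary steps):
#' `e[i, j] = (h/12) * sum_t (p_ij(t) + p_ij(t+1)) / 2`.
#'
#' @inheritParams occupancy_profile
#' @param integration `"trapezoid"` (default) or `"left"` (full credit for
#'   the step's starting occupancy).
#' @return 4 x 4 matrix (rows: starting state, columns: state).
#' @export
state_expectancies <- function(object, profile = NULL, start_age = 50,
                               integration = c("trapezoid", "left")) {
  bs <- .beta_spec(object)
  integration <- match.arg(integration)
  spec <- bs$spec
  h <- spec$step_months
  m0 <- as.integer(round(start_age * 12))
  n <- ceiling((spec$closure_age * 12 - m0) / h)
  if (n <= 0) {
    return(matrix(0, 4, 4, dimnames = list(start = .STATE_NAMES[1:4],
                                           state = .STATE_NAMES[1:4])))
  }
  cache <- .tm_cache(bs$beta, spec, profile)
  P <- cbind(diag(4), rep(0, 4))  # 4 starting indicators propagated together
  E <- matrix(0, 4, 4)
  w <- h / 12
  for (t in seq_len(n)) {
    Pn <- P %*% cache$getS(.age_key(m0 + h * (t - 1L), spec))
    E <- E + if (integration == "trapezoid") w * (P[, 1:4] + Pn[, 1:4]) / 2
             else w * P[, 1:4]
    P <- Pn
  }
  dimnames(E) <- list(start = .STATE_NAMES[1:4], state = .STATE_NAMES[1:4])
  E
}

#' Observed state prevalence near an index age
#'
#' Proportions of known-state observations with age within
#' `age +/- window/2`, using each subject's first observation only (so
#' frequent responders are not over-represented). State-0 observations are
#' excluded from numerator and denominator.
#'
#' @param dataset an `hwle_panel`.
#' @param age index age in years.
#' @param window total window width in years (default 5, i.e. +/- 2.5).
#' @param subset optional named list of covariate values the contributing
#'   observations must match (e.g. `list(oa = 0)`).
#' @return object of class `hwle_prevalence`: list with `age`, `pi` (named
#'   proportions over states 1-4), `window`, `n`.
#' @export
observed_prevalence <- function(dataset, age, window = 5, subset = NULL) {
  stopifnot(inherits(dataset, "hwle_panel"), window > 0)
  obs <- dataset$obs
  first <- obs[!duplicated(obs$id), , drop = FALSE]  # obs sorted by (id, age)
  sel <- first$state %in% 1:4 &
    first$age >= age - window / 2 & first$age <= age + window / 2
  if (!is.null(subset)) {
    for (nm in names(subset)) {
      sel <- sel & !is.na(first[[nm]]) & first[[nm]] == subset[[nm]]
    }
  }
  n <- sum(sel)
  if (n == 0) {
    stop(sprintf("no known-state observations within %.1f years of age %.1f; widen the window",
                 window / 2, age))
  }
  counts <- tabulate(first$state[sel], nbins = 4)
  structure(list(age = age, pi = setNames(counts / n, .STATE_NAMES[1:4]),
                 window = window, n = n),
            class = "hwle_prevalence")
}

#' @export
print.hwle_prevalence <- function(x, ...) {
  cat(sprintf("state prevalence at age %.1f (+/- %.2f y, n = %d):\n",
              x$age, x$window / 2, x$n))
  print(round(x$pi, 4))
  invisible(x)
}

#' Prevalence-weighted expectancies and total life expectancy
#'
#' `weighted[j] = sum_i pi[i] * e[i, j]`; `le = sum_j weighted[j]`. The
#' weighted expectancy of state 1 is HWLE.
#'
#' @param e 4 x 4 matrix from [state_expectancies()].
#' @param prevalence an `hwle_prevalence` or numeric vector of 4 proportions.
#' @return list with `weighted` (named length-4 vector) and `le`.
#' @export
weighted_expectancies <- function(e, prevalence) {
  pi <- if (inherits(prevalence, "hwle_prevalence")) prevalence$pi else prevalence
  stopifnot(length(pi) == 4, all(pi >= 0))
  if (abs(sum(pi) - 1) > 1e-8) stop("prevalence proportions must sum to 1")
  w <- as.vector(pi %*% e)
  list(weighted = setNames(w, .STATE_NAMES[1:4]), le = sum(w))
}

# draw coefficient arrays from the fitted sampling distribution
.coef_draws <- function(fit, n_draws, seed) {
  V <- fit$vcov
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (any(ev$values < -1e-8 * max(abs(ev$values), 1e-12))) {
    warning("covariance not positive semidefinite; clipped to the nearest PSD matrix")
  }
  vals <- pmax(ev$values, 0)
  Vpsd <- ev$vectors %*% (vals * t(ev$vectors))
  Vpsd <- (Vpsd + t(Vpsd)) / 2
  mean_nat <- unclass(fit$beta)[fit$par_index]
  set.seed(seed)
  draws <- MASS::mvrnorm(n_draws, mu = mean_nat, Sigma = Vpsd)
  if (n_draws == 1) draws <- matrix(draws, nrow = 1)
  draws
}

#' Simulation confidence intervals for expectancies
#'
#' Draws coefficient vectors from the fitted normal approximation
#' `N(beta_hat, vcov)`, recomputes the prevalence-weighted expectancies for
#' each draw and reports the 2.5/97.5 percentiles. Frozen cells stay at their
#' floor value. Reproducible under a fixed seed. The observed prevalence is
#' held fixed (its multinomial error is small relative to coefficient
#' uncertainty at survey sample sizes).
#'
#' @param fit an `hwle_fit`.
#' @param profile named covariate values.
#' @param start_age index age.
#' @param prevalence an `hwle_prevalence` or numeric vector of 4 proportions.
#' @param n_draws number of draws (default 1000).
#' @param seed RNG seed for the draws.
#' @return data.frame with rows HWLE, the other three state expectancies and
#'   LE; columns estimate, lower, upper, se.
#' @export
expectancy_ci <- function(fit, profile = NULL, start_age = 50, prevalence,
                          n_draws = 1000, seed = 1L) {
  stopifnot(inherits(fit, "hwle_fit"), n_draws >= 1)
  pi <- if (inherits(prevalence, "hwle_prevalence")) prevalence$pi else prevalence
  e0 <- state_expectancies(fit, profile, start_age)
  w0 <- weighted_expectancies(e0, pi)
  draws <- .coef_draws(fit, n_draws, seed)
  out <- matrix(NA_real_, n_draws, 5)
  b <- fit$beta
  for (r in seq_len(n_draws)) {
    b[fit$par_index] <- draws[r, ]
    e <- state_expectancies(list(beta = b, spec = fit$spec), profile, start_age)
    w <- weighted_expectancies(e, pi)
    out[r, ] <- c(w$weighted, w$le)
  }
  lo <- apply(out, 2, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(out, 2, stats::quantile, probs = 0.975, names = FALSE)
  se <- apply(out, 2, stats::sd)
  data.frame(quantity = c("hwle", "e2", "e3", "e4", "le"),
             estimate = c(w0$weighted, w0$le),
             lower = lo, upper = hi, se = se,
             stringsAsFactors = FALSE)
}

#' Expectancy table at an index age
#'
#' Assembles the unweighted expectancy matrix, the prevalence weights, the
#' weighted expectancies (HWLE = state 1), total LE and, when `n_draws > 0`,
#' simulation confidence intervals.
#'
#' @inheritParams expectancy_ci
#' @param dataset optional `hwle_panel` used to measure prevalence when
#'   `prevalence` is not supplied.
#' @param window prevalence window passed to [observed_prevalence()].
#' @param subset covariate filter for the prevalence observations (defaults
#'   to `profile` when the profile names dataset columns).
#' @return object of class `hwle_expectancy`.
#' @export
expectancy_table <- function(fit, dataset = NULL, prevalence = NULL,
                             profile = NULL, start_age = 50, window = 5,
                             subset = NULL, n_draws = 1000, seed = 1L) {
  stopifnot(inherits(fit, "hwle_fit"))
  if (is.null(prevalence)) {
    if (is.null(dataset)) stop("supply either prevalence or a dataset to measure it from")
    if (is.null(subset) && !is.null(profile)) {
      keep <- names(profile)[names(profile) %in% names(dataset$obs)]
      subset <- profile[keep]
    }
    prevalence <- observed_prevalence(dataset, start_age, window, subset = subset)
  }
  pi <- if (inherits(prevalence, "hwle_prevalence")) prevalence$pi else prevalence
  e <- state_expectancies(fit, profile, start_age)
  w <- weighted_expectancies(e, pi)
  ci <- if (n_draws > 0) {
    expectancy_ci(fit, profile, start_age, prevalence, n_draws = n_draws, seed = seed)
  } else NULL
  structure(list(start_age = start_age, profile = profile,
                 prevalence = prevalence, e = e,
                 weighted = w$weighted, le = w$le, ci = ci,
                 n_draws = n_draws, seed = seed),
            class = "hwle_expectancy")
}

#' @export
print.hwle_expectancy <- function(x, ...) {
  cat(sprintf("expectancies from age %s", format(x$start_age)))
  if (!is.null(x$profile) && length(x$profile)) {
    cat(" |", paste(names(x$profile), unlist(x$profile), sep = "=", collapse = ", "))
  }
  cat("\n")
  tab <- data.frame(years = round(c(x$weighted, LE = x$le), 2))
  if (!is.null(x$ci)) {
    tab$lower <- round(x$ci$lower, 2)
    tab$upper <- round(x$ci$upper, 2)
  }
  rownames(tab) <- c("HWLE (s1)", "s2", "s3", "s4", "LE")
  print(tab)
  invisible(x)
}

#' HWLE by age for one or more covariate profiles
#'
#' Applies the weighted pipeline at each age with prevalence measured at that
#' age (first observation per subject, same window throughout).
#'
#' @param fit an `hwle_fit`.
#' @param dataset an `hwle_panel` for prevalence measurement.
#' @param profiles named list of covariate profiles (each a named list);
#'   `list(all = NULL)` for a covariate-free model.
#' @param ages integer ages (default 50:75).
#' @param window prevalence window in years.
#' @return long data.frame: profile, age, n_prev, hwle, le.
#' @export
hwle_curve <- function(fit, dataset, profiles = list(all = NULL),
                       ages = 50:75, window = 5) {
  stopifnot(inherits(fit, "hwle_fit"))
  rows <- list()
  for (pn in names(profiles)) {
    profile <- profiles[[pn]]
    subset <- NULL
    if (!is.null(profile)) {
      keep <- names(profile)[names(profile) %in% names(dataset$obs)]
      subset <- profile[keep]
    }
    for (a in ages) {
      prev <- tryCatch(observed_prevalence(dataset, a, window, subset = subset),
                       error = function(e) NULL)
      if (is.null(prev)) next
      e <- state_expectancies(fit, profile, a)
      w <- weighted_expectancies(e, prev)
      rows[[length(rows) + 1L]] <- data.frame(
        profile = pn, age = a, n_prev = prev$n,
        hwle = w$weighted[1], le = w$le, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Health expectancy as a percentage of life expectancy
#'
#' @param hwle expectancy in years.
#' @param le life expectancy in years (must be positive).
#' @return percentage rounded to 1 decimal.
#' @examples
#' percent_of_le(5.68, 32.25)  # 17.6
#' @export
percent_of_le <- function(hwle, le) {
  if (any(le <= 0)) stop("le must be positive")
  round(100 * hwle / le, 1)
}
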