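#' Define a multi-state transition model specification
#'
#' The model has four live states plus death. For each origin state, movement
#' to each admissible destination over one interpolation step is a
#' multinomial logit with "stay in the origin state" as the reference
#' outcome. The linear predictor for each (origin, destination) cell is
#' `eta = sum_k beta[o,d,k] * x_k` over the model terms.
#'
#' Terms: `"intercept"` (always first), optionally `"age"` (years above 50 at
#' the step start; by default the nearest integer age, see `age_term`), then
#' named 0/1 covariates supplied per record.
#'
#' @param terms character vector of model terms; must start with
#'   `"intercept"`. Entries other than `"intercept"`/`"age"` name covariate
#'   columns.
#' @param adjacency 4 x 5 logical matrix (origins s1-s4 by destinations
#'   s1-s4, dead) marking admissible moves; the live diagonal must be FALSE
#'   (staying is the reference outcome, not a parameter). Default: all moves
#'   among live states and to death are admissible.
#' @param step_months interpolation step length in months (12 or 1).
#' @param closure_age age at which occupancy is truncated (default 110;
#'   residual live mass above it is negligible for any realistic mortality).
#' @param age_term `"nearest"` (integer age nearest the step start, the
#'   default: over a population with entry dates spread across the year the
#'   evaluation ages average out to the true age), `"floor"` (integer age at
#'   the step start, so probabilities are constant within each calendar year
#'   of age) or `"exact"` (fractional age).
#' @param death_snap how the month-precision death age maps to the step
#'   containing the death: `"floor"` (the step whose interval contains the
#'   death month, the default) or `"round"` (nearest whole step count, at
#'   least 1).
#' @return object of class `hwle_spec`.
#' @export
model_spec <- function(terms = c("intercept", "age"),
                       adjacency = full_adjacency(),
                       step_months = 12,
                       closure_age = 110,
                       age_term = c("nearest", "floor", "exact"),
                       death_snap = c("floor", "round")) {
  age_term <- match.arg(age_term)
  death_snap <- match.arg(death_snap)
  if (length(terms) < 1 || terms[1] != "intercept") {
    stop("terms must start with \"intercept\"")
  }
  if (anyDuplicated(terms)) stop("duplicate model terms")
  stopifnot(is.matrix(adjacency), nrow(adjacency) == 4, ncol(adjacency) == 5,
            is.logical(adjacency))
  if (any(diag(adjacency[, 1:4]))) {
    stop("the live diagonal of the adjacency must be FALSE (stay is the reference outcome)")
  }
  if (!step_months %in% c(1, 12)) stop("step_months must be 1 or 12")
  if (closure_age <= 50) stop("closure_age must exceed 50")
  dimnames(adjacency) <- list(origin = .STATE_NAMES[1:4], dest = .STATE_NAMES)
  structure(list(terms = terms,
                 adjacency = adjacency,
                 step_months = step_months,
                 closure_age = closure_age,
                 age_term = age_term,
                 death_snap = death_snap,
                 covariates = setdiff(terms, c("intercept", "age"))),
            class = "hwle_spec")
}

#' Default adjacency: all moves among live states, each live state to death
#'
#' Death is absorbing; the live diagonal is FALSE because staying put is the
#' reference outcome of each origin's multinomial logit.
#'
#' @return 4 x 5 logical matrix.
#' @export
full_adjacency <- function() {
  adj <- matrix(TRUE, 4, 5)
  diag(adj[, 1:4]) <- FALSE
  dimnames(adj) <- list(origin = .STATE_NAMES[1:4], dest = .STATE_NAMES)
  adj
}

#' @export
print.hwle_spec <- function(x, ...) {
  cat("hwle model spec\n")
  cat("  terms:", paste(x$terms, collapse = ", "), "\n")
  cat(sprintf("  step: %d month(s)   closure age: %s   age term: %s   death snap: %s\n",
              x$step_months, format(x$closure_age), x$age_term, x$death_snap))
  cat(sprintf("  admissible cells: %d of 20\n", sum(x$adjacency)))
  invisible(x)
}

#' Coefficient array template for a model specification
#'
#' Coefficients live in a 4 x 5 x K array indexed (origin, destination,
#' term); inadmissible cells are NA. A tidy data.frame representation is
#' available via [coef_to_df()] / [coef_from_df()].
#'
#' @param spec an `hwle_spec`.
#' @param value fill value for admissible cells (default 0).
#' @return array of class `hwle_coef`.
#' @export
coef_template <- function(spec, value = 0) {
  K <- length(spec$terms)
  b <- array(NA_real_, dim = c(4, 5, K),
             dimnames = list(origin = .STATE_NAMES[1:4],
                             dest = .STATE_NAMES,
                             term = spec$terms))
  for (o in 1:4) for (d in 1:5) if (spec$adjacency[o, d]) b[o, d, ] <- value
  structure(b, class = "hwle_coef")
}

#' Tidy representation of a coefficient array
#'
#' @param beta an `hwle_coef` array.
#' @return data.frame with columns origin, destination, term, value (one row
#'   per admissible coefficient).
#' @export
coef_to_df <- function(beta) {
  dn <- dimnames(beta)
  out <- expand.grid(origin = dn[[1]], destination = dn[[2]], term = dn[[3]],
                     stringsAsFactors = FALSE)
  out$value <- as.vector(beta)
  out[!is.na(out$value), , drop = FALSE]
}

#' Rebuild a coefficient array from its tidy representation
#'
#' @param df data.frame with columns origin, destination, term, value.
#' @param spec the matching `hwle_spec`.
#' @return an `hwle_coef` array.
#' @export
coef_from_df <- function(df, spec) {
  b <- coef_template(spec)
  for (i in seq_len(nrow(df))) {
    o <- match(df$origin[i], .STATE_NAMES[1:4])
    d <- match(df$destination[i], .STATE_NAMES)
    k <- match(df$term[i], spec$terms)
    if (is.na(o) || is.na(d) || is.na(k)) {
      stop("coefficient row does not match the spec: ",
           paste(df[i, 1:3], collapse = " / "))
    }
    if (!spec$adjacency[o, d]) stop("coefficient supplied for an inadmissible cell: ",
                                    df$origin[i], " -> ", df$destination[i])
    b[o, d, k] <- df$value[i]
  }
  b
}

#' Age value entering the linear predictor
#'
#' Under `"nearest"` (default) the age term is the integer age nearest the
#' step start; under `"floor"` it is the integer age at the step start, so
#' probabilities are constant within each year of age whatever the step
#' length; under `"exact"` the fractional age enters directly.
#'
#' @param age fractional age in years at the step start.
#' @param spec an `hwle_spec`.
#' @return numeric age value used in `eta`.
#' @export
age_covariate_value <- function(age, spec) {
  switch(spec$age_term,
         nearest = floor(age + 0.5 + 1e-9),
         floor = floor(age + 1e-9),
         exact = age)
}

# integer cache key of the design age for a step starting at month m;
# matrices are identical whenever the key agrees
.age_key <- function(m, spec) {
  switch(spec$age_term,
         nearest = (m + 6L) %/% 12L,
         floor = m %/% 12L,
         exact = as.integer(m))
}

# design age value (years) encoded by a key
.key_age <- function(key, spec) {
  if (spec$age_term == "exact") key / 12 else key
}

# design vector x_k for one step: intercept, (age - 50), covariates
.design_vector <- function(spec, age_value, profile) {
  K <- length(spec$terms)
  x <- numeric(K)
  for (k in seq_len(K)) {
    tm <- spec$terms[k]
    x[k] <- if (tm == "intercept") 1
    else if (tm == "age") age_value - 50
    else {
      v <- profile[[tm]]
      if (is.null(v) || is.na(v)) stop("profile does not supply covariate term: ", tm)
      as.numeric(v)
    }
  }
  x
}

#' One-step transition probability matrix
#'
#' Row `o` of the returned 5 x 5 matrix is the multinomial-logit step
#' distribution from origin `o`: for admissible destinations `d != o`,
#' `P[o,d] = exp(eta_od) / (1 + sum exp(eta_od'))` and
#' `P[o,o] = 1 / (1 + sum exp(eta_od'))`; masked destinations are exactly 0
#' and the dead row is the absorbing unit row.
#'
#' @param beta an `hwle_coef` array.
#' @param age age in years at the step start.
#' @param profile named list/vector of covariate values (may be empty when
#'   the spec has no covariate terms).
#' @param spec an `hwle_spec`.
#' @return 5 x 5 row-stochastic matrix.
#' @export
step_matrix <- function(beta, age, profile = NULL, spec) {
  x <- .design_vector(spec, age_covariate_value(age, spec), profile)
  .step_matrix_x(beta, x, spec)
}

.step_matrix_x <- function(beta, x, spec) {
  P <- matrix(0, 5, 5, dimnames = list(.STATE_NAMES, .STATE_NAMES))
  for (o in 1:4) {
    dests <- which(spec$adjacency[o, ])
    eta <- vapply(dests, function(d) sum(beta[o, d, ] * x), numeric(1))
    if (any(!is.finite(eta))) {
      stop(sprintf("non-finite linear predictor for cell %s -> %s",
                   .STATE_NAMES[o], .STATE_NAMES[dests[!is.finite(eta)][1]]))
    }
    ex <- exp(eta)
    denom <- 1 + sum(ex)
    P[o, dests] <- ex / denom
    P[o, o] <- 1 / denom
  }
  P[5, 5] <- 1
  P
}

# memoising cache of step matrices and their small powers for one
# (beta, spec, profile); keyed by the design-age key
.tm_cache <- function(beta, spec, profile) {
  S <- new.env(parent = emptyenv())
  POW <- new.env(parent = emptyenv())
  getS <- function(k) {
    key <- as.character(k)
    if (!is.null(S[[key]])) return(S[[key]])
    x <- .design_vector(spec, .key_age(k, spec), profile)
    m <- .step_matrix_x(beta, x, spec)
    S[[key]] <- m
    m
  }
  getPow <- function(a, k) {
    if (k == 1) return(getS(a))
    key <- paste0(a, ":", k)
    if (!is.null(POW[[key]])) return(POW[[key]])
    m <- getPow(a, k - 1L) %*% getS(a)
    POW[[key]] <- m
    m
  }
  list(getS = getS, getPow = getPow)
}

# product of n step matrices starting at origin month m0 (months of age),
# with the step at offset t evaluated via the spec's age convention
.interval_product <- function(cache, m0, n, h, spec) {
  M <- diag(5)
  if (n <= 0) return(M)
  keys <- .age_key(m0 + h * (0:(n - 1)), spec)
  r <- rle(keys)
  for (i in seq_along(r$values)) {
    M <- M %*% cache$getPow(r$values[i], r$lengths[i])
  }
  M
}

# cumulative products at several step counts (ascending), sharing work
.interval_products <- function(cache, m0, ns, h, spec) {
  ns <- sort(unique(ns))
  out <- vector("list", length(ns))
  names(out) <- as.character(ns)
  M <- diag(5)
  prev <- 0L
  for (j in seq_along(ns)) {
    n <- ns[j]
    if (n > prev) {
      keys <- .age_key(m0 + h * (prev:(n - 1L)), spec)
      r <- rle(keys)
      for (i in seq_along(r$values)) {
        M <- M %*% cache$getPow(r$values[i], r$lengths[i])
      }
      prev <- n
    }
    out[[j]] <- M
  }
  out
}

#' Transition matrix over an observed interval
#'
#' The interval `[age_from, age_to]` is divided into
#' `n = round((age_to - age_from) * 12 / step_months)` whole interpolation
#' steps (nearest whole step, ties to even) and the ordered product of the
#' step matrices is returned; `n = 0` gives the identity.
#'
#' @param beta an `hwle_coef` array.
#' @param age_from,age_to interval endpoints in years (`age_to >= age_from`).
#' @param profile named covariate values.
#' @param spec an `hwle_spec`.
#' @return 5 x 5 matrix (row-stochastic).
#' @export
interval_matrix <- function(beta, age_from, age_to, profile = NULL, spec) {
  if (age_to < age_from) stop("negative interval: age_to < age_from")
  h <- spec$step_months
  n <- round((age_to - age_from) * 12 / h)
  m0 <- as.integer(round(age_from * 12))
  cache <- .tm_cache(beta, spec, profile)
  M <- .interval_product(cache, m0, n, h, spec)
  dimnames(M) <- list(.STATE_NAMES, .STATE_NAMES)
  M
}
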