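# --- likelihood preparation -------------------------------------------------
#
# Records are aggregated once per fit into count groups keyed by covariate
# profile, origin month and step count. With an integer-valued age convention
# the step-matrix sequence of an interval depends only on the first step's
# design-age key and n, so identical intervals collapse into one weighted
# term and the cost of a likelihood evaluation is driven by the number of
# distinct groups, not the number of subjects.

.record_steps <- function(records, spec) {
  h <- spec$step_months
  m0 <- as.integer(round(records$origin_age * 12))
  n <- integer(nrow(records))
  live <- records$dest_kind %in% c("live", "unknown")
  if (any(live)) {
    dm <- as.integer(round(records$dest_age[live] * 12)) - m0[live]
    if (any(dm < 0)) stop("destination age precedes origin age")
    n[live] <- as.integer(round(dm / h))
  }
  dead <- records$dest_kind == "dead"
  if (any(dead)) {
    delta <- (records$dest_age[dead] * 12 - m0[dead]) / h
    if (any(delta < 0)) stop("death age precedes origin age")
    n[dead] <- if (spec$death_snap == "floor") {
      as.integer(floor(delta - 1e-9)) + 1L
    } else {
      pmax(1L, as.integer(round(delta)))
    }
  }
  list(m0 = m0, n = n)
}

# all step matrices for one profile over a set of design-age keys, built
# with vectorised linear algebra; returns a list parallel to `keys`
.step_array <- function(beta, spec, profile, keys) {
  K <- length(spec$terms)
  na <- length(keys)
  X <- matrix(0, na, K)
  for (k in seq_len(K)) {
    tm <- spec$terms[k]
    X[, k] <- if (tm == "intercept") 1
    else if (tm == "age") .key_age(keys, spec) - 50
    else {
      v <- profile[[tm]]
      if (is.null(v) || is.na(v)) stop("profile does not supply covariate term: ", tm)
      as.numeric(v)
    }
  }
  out <- vector("list", na)
  P0 <- matrix(0, 5, 5)
  P0[5, 5] <- 1
  for (i in seq_len(na)) out[[i]] <- P0
  for (o in 1:4) {
    dests <- which(spec$adjacency[o, ])
    nd <- length(dests)
    B <- matrix(unclass(beta)[.cell_index(rep(o, nd * K), rep(dests, K),
                                          rep(seq_len(K), each = nd))], nd, K)
    eta <- X %*% t(B)
    if (any(!is.finite(eta))) stop("non-finite linear predictor for origin ", .STATE_NAMES[o])
    ex <- exp(eta)
    denom <- 1 + rowSums(ex)
    for (i in seq_len(na)) {
      out[[i]][o, dests] <- ex[i, ] / denom[i]
      out[[i]][o, o] <- 1 / denom[i]
    }
  }
  out
}

# split the step sequence of one (origin month, needed step counts) group
# into run-length segments with snapshot markers, resolved once per fit
.group_plan <- function(m0, ns, h, spec) {
  cps <- ns[ns > 0L]
  plan <- vector("list", length(cps))
  prev <- 0L
  for (i in seq_along(cps)) {
    n <- cps[i]
    ts <- prev:(n - 1L)
    r <- rle(.age_key(m0 + h * ts, spec))
    plan[[i]] <- list(target = match(n, ns), key = r$values, len = r$lengths)
    prev <- n
  }
  plan
}

.prepare_likelihood <- function(records, spec) {
  use <- !records$excluded & records$dest_kind %in% c("live", "dead", "unknown")
  rec <- records[use, , drop = FALSE]
  if (!nrow(rec)) stop("no usable transition records after exclusions")
  st <- .record_steps(rec, spec)
  m0 <- st$m0; n <- st$n
  # zero-length live intervals: no information if the state is unchanged,
  # inconsistent data if it moved
  zero <- n == 0L & rec$dest_kind == "live"
  if (any(zero & rec$dest_state != rec$origin_state)) {
    stop("state change over an interval shorter than half a step")
  }
  drop <- (zero & rec$dest_state == rec$origin_state) |
    (n == 0L & rec$dest_kind == "unknown")
  rec <- rec[!drop, , drop = FALSE]; m0 <- m0[!drop]; n <- n[!drop]
  if (!nrow(rec)) stop("no usable transition records after exclusions")

  h <- spec$step_months
  # yearly steps with an integer age convention: the key sequence is fixed by
  # the first step's key, so merge groups onto a canonical origin month
  m0key <- if (h == 12 && spec$age_term != "exact") .age_key(m0, spec) * 12L else m0
  covs <- spec$covariates
  pkey <- if (length(covs)) {
    do.call(paste, c(lapply(covs, function(cv) rec[[cv]]), sep = "|"))
  } else rep("", nrow(rec))
  kind <- match(rec$dest_kind, c("live", "dead", "unknown"))
  dest <- ifelse(kind == 1L, rec$dest_state, ifelse(kind == 2L, 5L, NA_integer_))

  key <- paste(pkey, m0key, rec$origin_state, kind, dest, n, sep = "#")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, "#", fixed = TRUE)
  gd <- data.frame(
    pkey = vapply(parts, `[[`, "", 1),
    m0 = as.integer(vapply(parts, `[[`, "", 2)),
    origin = as.integer(vapply(parts, `[[`, "", 3)),
    kind = as.integer(vapply(parts, `[[`, "", 4)),
    dest = suppressWarnings(as.integer(vapply(parts, `[[`, "", 5))),
    n = as.integer(vapply(parts, `[[`, "", 6)),
    count = agg$Freq,
    stringsAsFactors = FALSE
  )

  first_of_profile <- match(unique(gd$pkey), pkey)
  profiles <- lapply(first_of_profile, function(i) {
    as.list(setNames(lapply(covs, function(cv) as.numeric(rec[[cv]][i])), covs))
  })
  names(profiles) <- unique(gd$pkey)

  blocks <- lapply(names(profiles), function(pk) {
    sub <- gd[gd$pkey == pk, , drop = FALSE]
    groups <- lapply(split(sub, sub$m0), function(s) {
      ns <- sort(unique(c(s$n, s$n[s$kind == 2L] - 1L)))
      ns <- ns[ns >= 0L]
      list(ns = ns,
           plan = .group_plan(s$m0[1], ns, h, spec),
           origin = s$origin, kind = s$kind, dest = s$dest,
           nidx = match(s$n, ns),
           nprev = ifelse(s$kind == 2L, match(s$n - 1L, ns), 0L),
           count = s$count)
    })
    keys <- sort(unique(unlist(lapply(groups, function(g) {
      unlist(lapply(g$plan, `[[`, "key"))
    }))))
    # resolve key lookups to positions once
    groups <- lapply(groups, function(g) {
      g$plan <- lapply(g$plan, function(iv) {
        iv$ioff <- match(iv$key, keys)
        iv
      })
      g
    })
    list(profile = profiles[[pk]], groups = groups, keys = keys)
  })

  # per-cell observed event counts (live moves and deaths pin cells)
  events <- matrix(0L, 4, 5, dimnames = list(.STATE_NAMES[1:4], .STATE_NAMES))
  ev <- gd[gd$kind %in% c(1L, 2L) & gd$dest != gd$origin, , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    events[ev$origin[i], ev$dest[i]] <- events[ev$origin[i], ev$dest[i]] + ev$count[i]
  }
  # crude person-steps at risk by origin (records attributed wholly to origin)
  risk_steps <- vapply(1:4, function(o) {
    sum(gd$count[gd$origin == o] * gd$n[gd$origin == o])
  }, numeric(1))

  list(blocks = blocks, n_used = sum(gd$count), events = events,
       risk_steps = risk_steps)
}

.loglik_prepared <- function(beta, spec, prep) {
  ll <- 0
  I5 <- diag(5)
  for (blk in prep$blocks) {
    S <- .step_array(beta, spec, blk$profile, blk$keys)
    Pow <- vector("list", length(S))  # lazily grown powers for monthly runs
    for (g in blk$groups) {
      snaps <- vector("list", length(g$ns))
      M <- I5
      if (g$ns[1] == 0L) snaps[[1]] <- M
      for (iv in g$plan) {
        for (j in seq_along(iv$ioff)) {
          ioff <- iv$ioff[j]
          len <- iv$len[j]
          if (len == 1L) {
            M <- M %*% S[[ioff]]
          } else {
            p <- Pow[[ioff]]
            if (is.null(p)) p <- list(S[[ioff]])
            while (length(p) < len) p[[length(p) + 1L]] <- p[[length(p)]] %*% S[[ioff]]
            Pow[[ioff]] <- p
            M <- M %*% p[[len]]
          }
        }
        snaps[[iv$target]] <- M
      }
      o <- g$origin
      for (i in seq_along(o)) {
        Mi <- snaps[[g$nidx[i]]]
        p <- if (g$kind[i] == 1L) Mi[o[i], g$dest[i]]
        else if (g$kind[i] == 2L) Mi[o[i], 5L] - snaps[[g$nprev[i]]][o[i], 5L]
        else Mi[o[i], 1L] + Mi[o[i], 2L] + Mi[o[i], 3L] + Mi[o[i], 4L]
        ll <- ll + g$count[i] * log(max(p, 1e-300))
      }
    }
  }
  ll
}

#' Log-likelihood contribution of one transition record
#'
#' A live destination contributes the log of the corresponding interval-matrix
#' entry; an `"unknown"` destination (state observed as 0) contributes the log
#' probability of being in any live state (survival only); a `"dead"` record
#' contributes the log probability of surviving to the step containing the
#' death month and dying within it; a `"censored"` record contributes 0.
#'
#' @param beta an `hwle_coef` array.
#' @param record list or one-row data.frame with `origin_state`, `origin_age`,
#'   `dest_kind` ("live"/"dead"/"unknown"/"censored"), `dest_state`,
#'   `dest_age` and any covariates named by the spec.
#' @param spec an `hwle_spec`.
#' @return log-probability (scalar).
#' @export
transition_loglik <- function(beta, record, spec) {
  record <- as.list(record)
  o <- record$origin_state
  if (!o %in% 1:4) stop("record origin state must lie in 1..4")
  if (identical(record$dest_kind, "censored")) return(0)
  profile <- record[spec$covariates]
  h <- spec$step_months
  m0 <- as.integer(round(record$origin_age * 12))
  cache <- .tm_cache(beta, spec, profile)
  if (record$dest_kind == "dead") {
    delta <- (record$dest_age * 12 - m0) / h
    n <- if (spec$death_snap == "floor") as.integer(floor(delta - 1e-9)) + 1L
         else pmax(1L, as.integer(round(delta)))
    Mn <- .interval_product(cache, m0, n, h, spec)
    p <- Mn[o, 5] - (if (n > 1L) .interval_product(cache, m0, n - 1L, h, spec)[o, 5] else 0)
  } else {
    n <- as.integer(round((record$dest_age - record$origin_age) * 12 / h))
    M <- .interval_product(cache, m0, n, h, spec)
    p <- if (record$dest_kind == "unknown") sum(M[o, 1:4]) else M[o, record$dest_state]
  }
  if (p <= 0) {
    stop(sprintf(
      "observed transition %s (age %.2f) -> %s has zero probability under the adjacency mask",
      .STATE_NAMES[o], record$origin_age,
      if (record$dest_kind == "live") .STATE_NAMES[record$dest_state] else record$dest_kind))
  }
  as.numeric(log(p))
}

#' Total log-likelihood of a dataset
#'
#' Sums [transition_loglik()] over the records that survive covariate
#' exclusion (observations with incomplete covariate data are ignored, as are
#' records whose origin state is unknown or below age 50).
#'
#' @param beta an `hwle_coef` array.
#' @param dataset an `hwle_panel`, or a record data.frame from
#'   [extract_transitions()].
#' @param spec an `hwle_spec`.
#' @param survivors survivor handling passed to [extract_transitions()].
#' @return scalar log-likelihood with attribute `n_used` (records entering
#'   the sum).
#' @export
total_loglik <- function(beta, dataset, spec,
                         survivors = c("linkage_end", "last_interview")) {
  records <- if (inherits(dataset, "hwle_panel")) {
    extract_transitions(dataset, covariates = spec$covariates,
                        survivors = match.arg(survivors))
  } else dataset
  prep <- .prepare_likelihood(records, spec)
  structure(.loglik_prepared(beta, spec, prep), n_used = prep$n_used)
}

# linear indices of cell (o,d) term k in the 4 x 5 x K array
.cell_index <- function(o, d, k) (k - 1L) * 20L + (d - 1L) * 4L + o

#' Fit the transition model by maximum likelihood
#'
#' Maximises the interval-censored likelihood with a bounded quasi-Newton
#' search (`optim` L-BFGS-B, coefficients bounded in \[-30, 30\] on the
#' optimiser scale). Internally the age term is scaled to (age - 50)/10 for
#' conditioning; estimates and covariance are reported on the natural scale
#' (per year of age above 50). The covariance is the inverse of the
#' numerically differentiated observed information; if that matrix is
#' singular a pseudo-inverse is used with a warning. Admissible cells with no
#' observed events are frozen at intercept -30 (step probability ~ 0) and
#' excluded from the search.
#'
#' @param dataset an `hwle_panel` or a record data.frame from
#'   [extract_transitions()].
#' @param spec an `hwle_spec`.
#' @param init optional `hwle_coef` array of starting values.
#' @param control list passed to `optim` (default `maxit = 600`).
#' @param survivors survivor handling passed to [extract_transitions()].
#' @return object of class `hwle_fit`: spec, `beta` (an `hwle_coef`), `vcov`
#'   (natural scale, free parameters), `par` (tidy table with estimates and
#'   standard errors), `frozen` (cells held at the floor), `loglik`,
#'   `n_used`, `exclusions` and `diagnostics`.
#' @export
fit_mle <- function(dataset, spec, init = NULL, control = list(),
                    survivors = c("linkage_end", "last_interview")) {
  records <- if (inherits(dataset, "hwle_panel")) {
    extract_transitions(dataset, covariates = spec$covariates,
                        survivors = match.arg(survivors))
  } else dataset
  prep <- .prepare_likelihood(records, spec)

  K <- length(spec$terms)
  adm <- which(spec$adjacency, arr.ind = TRUE)
  active <- adm[prep$events[adm] > 0L, , drop = FALSE]
  frozen <- adm[prep$events[adm] == 0L, , drop = FALSE]
  if (!nrow(active)) stop("no admissible cell has observed events")

  par_info <- do.call(rbind, lapply(seq_len(nrow(active)), function(i) {
    data.frame(origin = .STATE_NAMES[active[i, 1]],
               destination = .STATE_NAMES[active[i, 2]],
               term = spec$terms, o = active[i, 1], d = active[i, 2],
               k = seq_len(K), stringsAsFactors = FALSE)
  }))
  par_info$index <- .cell_index(par_info$o, par_info$d, par_info$k)
  scale <- ifelse(par_info$term == "age", 10, 1)  # theta = scale * beta
  pnames <- sprintf("%s->%s:%s", par_info$origin, par_info$destination, par_info$term)

  base <- coef_template(spec, value = 0)
  if (nrow(frozen)) {
    for (i in seq_len(nrow(frozen))) {
      base[frozen[i, 1], frozen[i, 2], ] <- 0
      base[frozen[i, 1], frozen[i, 2], 1] <- -30
    }
    message(sprintf("%d admissible cell(s) without observed events frozen at intercept -30",
                    nrow(frozen)))
  }

  theta0 <- if (!is.null(init)) {
    unclass(init)[par_info$index] * scale
  } else {
    # crude per-step event rates give intercept starting values in the right
    # order of magnitude; slopes start at zero
    crude <- log(pmax(prep$events[cbind(par_info$o, par_info$d)] /
                        pmax(prep$risk_steps[par_info$o], 1), 1e-4))
    ifelse(par_info$term == "intercept", pmin(pmax(crude, -9), -0.5), 0)
  }

  fill_beta <- function(theta) {
    b <- base
    b[par_info$index] <- theta / scale
    b
  }
  negll <- function(theta) {
    v <- -.loglik_prepared(fill_beta(theta), spec, prep)
    if (!is.finite(v)) 1e10 else v
  }

  ctl <- modifyList(list(maxit = 600, factr = 1e9), control)
  opt <- stats::optim(theta0, negll, method = "L-BFGS-B",
                      lower = -30, upper = 30, control = ctl)
  if (opt$convergence != 0) {
    stop("optimiser did not converge: code ", opt$convergence, " (", opt$message, ")")
  }

  # diagnostics: central-difference gradient on the optimiser scale
  p <- length(opt$par)
  grad <- numeric(p)
  for (i in seq_len(p)) {
    e <- 1e-5 * max(1, abs(opt$par[i]))
    tp <- opt$par; tp[i] <- tp[i] + e
    tm <- opt$par; tm[i] <- tm[i] - e
    grad[i] <- (negll(tp) - negll(tm)) / (2 * e)
  }

  H <- stats::optimHess(opt$par, negll, control = list(ndeps = rep(1e-4, p)))
  V <- tryCatch(solve(H), error = function(e) NULL)
  singular <- is.null(V) || any(!is.finite(V)) || any(diag(V) < 0)
  if (singular) {
    warning("observed information is singular or indefinite; using a pseudo-inverse")
    V <- MASS::ginv(H)
  }
  Tm <- diag(1 / scale, p)
  V_nat <- Tm %*% V %*% Tm
  dimnames(V_nat) <- list(pnames, pnames)

  beta_hat <- fill_beta(opt$par)
  par_tab <- data.frame(origin = par_info$origin,
                        destination = par_info$destination,
                        term = par_info$term,
                        estimate = opt$par / scale,
                        std_error = sqrt(pmax(diag(V_nat), 0)),
                        stringsAsFactors = FALSE)

  structure(list(
    spec = spec,
    beta = beta_hat,
    vcov = V_nat,
    par = par_tab,
    par_index = par_info$index,
    frozen = if (nrow(frozen)) data.frame(origin = .STATE_NAMES[frozen[, 1]],
                                          destination = .STATE_NAMES[frozen[, 2]],
                                          stringsAsFactors = FALSE)
             else data.frame(origin = character(), destination = character()),
    loglik = -opt$value,
    n_used = prep$n_used,
    exclusions = attr(records, "exclusions"),
    diagnostics = list(convergence = opt$convergence,
                       iterations = opt$counts,
                       grad_norm = sqrt(sum(grad^2)),
                       covariance_pseudo_inverse = singular)
  ), class = "hwle_fit")
}

#' @export
print.hwle_fit <- function(x, ...) {
  cat("hwle fitted transition model\n")
  cat(sprintf("  log-likelihood: %.3f on %d records (%d free parameters)\n",
              x$loglik, x$n_used, nrow(x$par)))
  if (nrow(x$frozen)) {
    cat("  frozen cells:",
        paste(sprintf("%s->%s", x$frozen$origin, x$frozen$destination), collapse = ", "), "\n")
  }
  cat(sprintf("  gradient norm at optimum: %.3g\n", x$diagnostics$grad_norm))
  invisible(x)
}

#' @export
coef.hwle_fit <- function(object, ...) object$par

#' @export
vcov.hwle_fit <- function(object, ...) object$vcov

#' @export
logLik.hwle_fit <- function(object, ...) {
  structure(object$loglik, df = nrow(object$par), class = "logLik")
}
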