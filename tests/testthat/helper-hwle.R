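# shared builders for small deterministic fixtures

# adjacency where each live state can only die (no live-live movement)
death_only_adjacency <- function() {
  adj <- matrix(FALSE, 4, 5)
  adj[, 5] <- TRUE
  dimnames(adj) <- list(origin = c("s1", "s2", "s3", "s4"),
                        dest = c("s1", "s2", "s3", "s4", "dead"))
  adj
}

# two-state (alive/dead) reduction: intercept-only, per-step death
# probability q for every live origin
two_state_spec <- function(step_months = 12, closure_age = 110) {
  model_spec(terms = "intercept", adjacency = death_only_adjacency(),
             step_months = step_months, closure_age = closure_age)
}
two_state_beta <- function(q, spec = two_state_spec()) {
  b <- coef_template(spec)
  b[, 5, 1] <- qlogis(q)
  b
}

# intercept-only full-adjacency coefficients drawn at random; death kept
# heavy so occupancy vanishes well before closure
random_homogeneous_beta <- function(spec, seed, live_mean = -2.5, dead_mean = 0) {
  set.seed(seed)
  b <- coef_template(spec)
  for (o in 1:4) for (d in which(spec$adjacency[o, ])) {
    b[o, d, 1] <- rnorm(1, if (d == 5L) dead_mean else live_mean, 0.4)
  }
  b
}

# minimal panel from per-subject state/age vectors
make_panel <- function(states, ages, death_age = NULL, covariates = character(),
                       extra = NULL) {
  stopifnot(is.list(states), is.list(ages))
  obs <- do.call(rbind, lapply(seq_along(states), function(i) {
    d <- data.frame(id = i, wave = seq_along(states[[i]]),
                    age = ages[[i]], state = states[[i]])
    if (!is.null(extra)) for (nm in names(extra)) d[[nm]] <- extra[[nm]][[i]]
    d
  }))
  vital <- data.frame(id = seq_along(states),
                      death_age = if (is.null(death_age)) NA_real_ else death_age,
                      followup_end_age = vapply(ages, max, numeric(1)))
  panel_dataset(obs, vital, covariates = covariates)
}

# hand-built transition records (as extract_transitions would emit)
make_records <- function(df) {
  df$excluded <- FALSE
  df$exclude_reason <- NA_character_
  if (is.null(df$id)) df$id <- seq_len(nrow(df))
  df
}
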