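#' Default generating model specification for synthetic cohorts
#'
#' Multinomial-logit transition model with intercept, age and a binary
#' osteoarthritis covariate over the full adjacency, yearly interpolation
#' steps, closure at 110.
#'
#' @return an `hwle_spec`.
#' @export
default_sim_spec <- function() {
  model_spec(terms = c("intercept", "age", "oa"), step_months = 12)
}

#' Default generating coefficients
#'
#' Read from the versioned fixture `inst/extdata/beta_true_default.csv`.
#' The values are calibrated so that, under the default entry-state mix,
#' population HWLE at 50 lies around 7-10 years and LE around 28-32 years —
#' the magnitudes observed in English panel studies of later working life.
#'
#' @param spec the matching `hwle_spec` (default [default_sim_spec()]).
#' @return an `hwle_coef` array.
#' @export
default_beta <- function(spec = default_sim_spec()) {
  path <- system.file("extdata", "beta_true_default.csv", package = "hwle")
  if (path == "") path <- file.path("inst", "extdata", "beta_true_default.csv")
  coef_from_df(utils::read.csv(path, stringsAsFactors = FALSE), spec)
}

#' Simulation configuration for a synthetic panel cohort
#'
#' Presets emulate the structure of the two study designs the estimator is
#' aimed at: `"elsa_like"` (six waves two years apart, refreshment entry at
#' waves 3/4/6, occupation unmeasured at wave 1, time-dependent
#' osteoarthritis self-report, 10-year mortality linkage) and
#' `"norstop_like"` (baseline + 3- and 6-year follow-ups, fixed
#' osteoarthritis flag, mortality observed to the 6-year end).
#'
#' @param preset `"elsa_like"` or `"norstop_like"`.
#' @param n_subjects cohort size.
#' @param seed master seed; spawns per-subject seeds deterministically so
#'   cohorts are reproducible and order-independent.
#' @param beta_true generating coefficients (default [default_beta()]).
#' @param spec generating `hwle_spec` (default [default_sim_spec()]).
#' @param ... overrides for any default field (e.g. `attrition_prob`,
#'   `state_missing_prob`, `wave_offsets`, `init_state_probs`).
#' @return object of class `hwle_sim_config`.
#' @export
sim_config <- function(preset = c("elsa_like", "norstop_like"),
                       n_subjects = 1000, seed = 1L,
                       beta_true = NULL, spec = NULL, ...) {
  preset <- match.arg(preset)
  if (is.null(spec)) spec <- default_sim_spec()
  if (is.null(beta_true)) beta_true <- default_beta(spec)
  cfg <- list(
    preset = preset,
    n_subjects = n_subjects,
    seed = as.integer(seed),
    beta_true = beta_true,
    spec = spec,
    entry_age_range = c(50, 90),
    init_state_probs = c(0.55, 0.23, 0.08, 0.14),
    sex_prob = 0.5,
    occupation_probs = c(self_employed = 0.1, non_manual = 0.5, manual = 0.4),
    attrition_prob = 0.10,
    state_missing_prob = 0.05
  )
  if (preset == "elsa_like") {
    cfg <- c(cfg, list(
      wave_offsets = c(0, 2, 4, 6, 8, 10),
      entry_waves = c(1, 3, 4, 6),
      entry_wave_probs = c(0.7, 0.1, 0.1, 0.1),
      oa_mode = "time_dependent",
      oa_prev50 = 0.25,
      oa_onset_rate = 0.02,
      covariate_missing_prob = 0.03,
      occupation_wave1_missing = TRUE,
      linkage_end_years = 10
    ))
  } else {
    cfg <- c(cfg, list(
      wave_offsets = c(0, 3, 6),
      entry_waves = 1,
      entry_wave_probs = 1,
      oa_mode = "fixed",
      oa_flag_prob = 0.3,
      covariate_missing_prob = 0,
      occupation_wave1_missing = FALSE,
      linkage_end_years = 6
    ))
  }
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  stopifnot(abs(sum(cfg$init_state_probs) - 1) < 1e-8,
            all(diff(cfg$wave_offsets) > 0))
  class(cfg) <- "hwle_sim_config"
  cfg
}

# covariate profile of a subject at a given age, for the generating spec
.subject_profile <- function(cfg, sub, age) {
  out <- list()
  for (cv in cfg$spec$covariates) {
    out[[cv]] <- switch(cv,
      oa = as.numeric(if (cfg$oa_mode == "fixed") sub$oa_flag else age >= sub$oa_onset_age),
      sex = as.numeric(sub$sex),
      stopifnot("unsupported generating covariate" = FALSE))
  }
  out
}

# shared memo of step matrices for the cohort; keyed (design-age key, profile)
.sim_cache <- function(cfg) {
  env <- new.env(parent = emptyenv())
  function(mt, profile) {
    key <- paste(.age_key(mt, cfg$spec), paste(unlist(profile), collapse = "|"), sep = "@")
    m <- env[[key]]
    if (is.null(m)) {
      m <- step_matrix(cfg$beta_true, mt / 12, profile, cfg$spec)
      env[[key]] <- m
    }
    m
  }
}

#' Simulate one subject's latent trajectory
#'
#' The latent state path evolves on the generating model's own step grid,
#' aligned to the subject's fractional entry age, by sampling each step from
#' [step_matrix()] at the current age and covariate profile. Osteoarthritis
#' switches on permanently at its sampled onset age (time-dependent mode) or
#' is a fixed flag. Subjects are conditioned on being alive at their entry
#' age (rejection sampling), matching a panel that only recruits survivors.
#' The path ends at death (with a month-precision death age inside the fatal
#' step) or at the closure age.
#'
#' @param config an `hwle_sim_config`.
#' @param subject_seed integer seed; identical seeds give identical paths.
#' @param cache optional shared step-matrix memo (internal speed-up).
#' @return list with `entry_age`, `entry_wave`, `m00` (grid origin in months
#'   of age), `states` (latent state at each grid point), `death_age` (NA if
#'   alive at closure), covariates (`sex`, `occupation`, `oa_flag` or
#'   `oa_onset_age`).
#' @export
simulate_subject <- function(config, subject_seed, cache = NULL) {
  cfg <- config
  if (is.null(cache)) cache <- .sim_cache(cfg)
  set.seed(subject_seed)
  h <- cfg$spec$step_months
  closure_m <- as.integer(round(cfg$spec$closure_age * 12))
  for (try in 1:1000) {
    em_grid <- seq(as.integer(round(cfg$entry_age_range[1] * 12)),
                   as.integer(round(cfg$entry_age_range[2] * 12)))
    em <- em_grid[sample.int(length(em_grid), 1)]
    entry_age <- em / 12
    m00 <- 600L + (em - 600L) %% 12L  # latent grid starts at ~50 + entry month offset
    entry_wave <- if (length(cfg$entry_waves) == 1) cfg$entry_waves else {
      sample(cfg$entry_waves, 1, prob = cfg$entry_wave_probs)
    }
    sub <- list(
      sex = stats::rbinom(1, 1, cfg$sex_prob),
      occupation = sample(names(cfg$occupation_probs), 1, prob = cfg$occupation_probs)
    )
    if (cfg$oa_mode == "fixed") {
      sub$oa_flag <- stats::rbinom(1, 1, cfg$oa_flag_prob)
    } else {
      sub$oa_onset_age <- if (stats::rbinom(1, 1, cfg$oa_prev50) == 1) 50
                          else 50 + stats::rexp(1, cfg$oa_onset_rate)
    }
    state <- sample.int(4, 1, prob = cfg$init_state_probs)
    states <- integer(0)
    death_age <- NA_real_
    t <- 0L
    repeat {
      states[t + 1L] <- state
      mt <- m00 + h * t
      if (mt >= closure_m) break
      S <- cache(mt, .subject_profile(cfg, sub, mt / 12))
      nxt <- sample.int(5L, 1L, prob = S[state, ])
      if (nxt == 5L) {
        death_age <- (mt + (sample.int(h, 1) - 0.5)) / 12
        break
      }
      state <- nxt
      t <- t + 1L
    }
    if (is.na(death_age) || death_age > entry_age) {
      sub$entry_age <- entry_age
      sub$entry_wave <- entry_wave
      sub$m00 <- m00
      sub$states <- states
      sub$death_age <- death_age
      return(sub)
    }
  }
  stop("could not simulate a subject alive at entry after 1000 attempts")
}

#' Observe a latent trajectory at scheduled waves
#'
#' Emits one observation per scheduled wave the subject survives and attends:
#' permanent dropout with the attrition probability at each wave after the
#' first, state recorded as 0 with the state-missingness probability, the
#' osteoarthritis covariate missing with the covariate-missingness
#' probability, and occupation unmeasured at wave 1 when the preset says so.
#' A death within the mortality-linkage window yields a vital record with
#' the month-precision death age.
#'
#' @param subject output of [simulate_subject()].
#' @param config the `hwle_sim_config`.
#' @param seed integer seed for the observation-process draws.
#' @param id subject identifier for the emitted rows.
#' @return list with `obs` (data.frame of observations) and `vital`
#'   (one-row data.frame).
#' @export
observe_waves <- function(subject, config, seed, id = 1L) {
  cfg <- config
  sub <- subject
  set.seed(seed)
  h <- cfg$spec$step_months
  offs <- cfg$wave_offsets
  ew <- sub$entry_wave
  rows <- list()
  for (w in seq(ew, length(offs))) {
    if (w > ew && stats::runif(1) < cfg$attrition_prob) break
    aw <- sub$entry_age + (offs[w] - offs[ew])
    if (!is.na(sub$death_age) && sub$death_age <= aw) break
    idx <- (as.integer(round(aw * 12)) - sub$m00) %/% h + 1L
    if (idx < 1L || idx > length(sub$states)) break
    st <- sub$states[idx]
    if (stats::runif(1) < cfg$state_missing_prob) st <- 0L
    oa <- if (cfg$oa_mode == "fixed") sub$oa_flag else as.numeric(aw >= sub$oa_onset_age)
    if (stats::runif(1) < cfg$covariate_missing_prob) oa <- NA_real_
    occ <- if (w == 1L && cfg$occupation_wave1_missing) NA_character_ else sub$occupation
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, wave = w, age = aw, state = st,
      oa = oa, sex = sub$sex, occupation = occ,
      stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, rows)
  cal_death <- if (is.na(sub$death_age)) NA_real_ else offs[ew] + (sub$death_age - sub$entry_age)
  death_obs <- if (!is.na(cal_death) && cal_death <= cfg$linkage_end_years) sub$death_age else NA_real_
  vital <- data.frame(id = id, death_age = death_obs,
                      followup_end_age = sub$entry_age + (cfg$linkage_end_years - offs[ew]),
                      stringsAsFactors = FALSE)
  list(obs = obs, vital = vital)
}

#' Generate a synthetic panel cohort with its truth record
#'
#' Runs [simulate_subject()] and [observe_waves()] for `n_subjects` subjects
#' under deterministically spawned per-subject seeds and assembles the
#' resulting panel. The truth record carries the generating coefficients and
#' the exact state expectancies at age 50 implied by them (computed with the
#' expectancies module at `beta_true`), enabling parameter- and
#' expectancy-recovery studies.
#'
#' @param config an `hwle_sim_config`.
#' @return list with `dataset` (an `hwle_panel`), `truth` (list: `beta_true`,
#'   `spec`, `init_state_probs`, per-profile `e50`, `hwle50`, `le50`) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "hwle_sim_config"))
  set.seed(cfg$seed)
  seeds_sim <- sample.int(.Machine$integer.max - 1L, cfg$n_subjects)
  seeds_obs <- sample.int(.Machine$integer.max - 1L, cfg$n_subjects)
  cache <- .sim_cache(cfg)
  obs_list <- vector("list", cfg$n_subjects)
  vital_list <- vector("list", cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    sub <- simulate_subject(cfg, seeds_sim[i], cache = cache)
    ow <- observe_waves(sub, cfg, seeds_obs[i], id = i)
    obs_list[[i]] <- ow$obs
    vital_list[[i]] <- ow$vital
  }
  dataset <- panel_dataset(do.call(rbind, obs_list), do.call(rbind, vital_list),
                           covariates = c("oa", "sex", "occupation"))

  profiles <- if ("oa" %in% cfg$spec$covariates) {
    list(no_oa = list(oa = 0), oa = list(oa = 1))
  } else list(all = NULL)
  e50 <- lapply(profiles, function(p) {
    state_expectancies(list(beta = cfg$beta_true, spec = cfg$spec), p, 50)
  })
  hwle50 <- vapply(e50, function(e) sum(cfg$init_state_probs * e[, 1]), numeric(1))
  le50 <- vapply(e50, function(e) sum(cfg$init_state_probs %*% e), numeric(1))
  truth <- list(beta_true = cfg$beta_true, spec = cfg$spec,
                init_state_probs = cfg$init_state_probs,
                profiles = profiles, e50 = e50,
                hwle50 = hwle50, le50 = le50)
  list(dataset = dataset, truth = truth, config = cfg)
}
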