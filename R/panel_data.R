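#' Construct a panel dataset
#'
#' Bundles long-format observations, vital records and a covariate schema into
#' the container consumed by the likelihood. Validation is run on
#' construction; structural problems (non-increasing ages, observations after
#' death, invalid state codes) are errors, while records below the analysis
#' age floor of 50 are flagged in the validation summary rather than silently
#' used.
#'
#' @param obs data.frame with columns `id`, `wave`, `age`, `state` (0:4) plus
#'   one column per covariate.
#' @param vital data.frame with columns `id`, `death_age` (NA if alive at
#'   linkage end), `followup_end_age`. Subjects absent from `vital` are
#'   treated as alive with follow-up ending at their last observation.
#' @param covariates character vector naming the covariate columns of `obs`.
#' @return object of class `hwle_panel`: list with elements `obs`, `vital`,
#'   `covariates` and a `validation` summary (counts of subjects,
#'   observations, deaths, under-age records).
#' @export
panel_dataset <- function(obs, vital = NULL, covariates = character()) {
  need <- c("id", "wave", "age", "state")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("obs is missing mandatory column(s): ", paste(miss, collapse = ", "))
  miss_cov <- setdiff(covariates, names(obs))
  if (length(miss_cov)) stop("covariate column(s) not present in obs: ", paste(miss_cov, collapse = ", "))
  obs <- obs[order(obs$id, obs$age), , drop = FALSE]
  rownames(obs) <- NULL
  if (!all(obs$state %in% 0:4)) stop("state codes must lie in 0:4")
  dup <- duplicated(obs[c("id", "wave")])
  if (any(dup)) {
    d <- obs[dup, c("id", "wave")]
    stop("duplicate (subject, wave) record(s): ",
         paste(sprintf("(id=%s, wave=%s)", d$id, d$wave), collapse = ", "))
  }
  bad_age <- tapply(obs$age, obs$id, function(a) any(diff(a) <= 0))
  if (any(unlist(bad_age))) {
    stop("ages not strictly increasing for subject(s): ",
         paste(names(bad_age)[unlist(bad_age)], collapse = ", "))
  }
  if (is.null(vital)) {
    vital <- data.frame(id = unique(obs$id), death_age = NA_real_,
                        followup_end_age = tapply(obs$age, obs$id, max)[as.character(unique(obs$id))])
  }
  if (!all(c("id", "death_age") %in% names(vital))) {
    stop("vital is missing mandatory column(s): id, death_age")
  }
  if (!"followup_end_age" %in% names(vital)) vital$followup_end_age <- NA_real_
  if (anyDuplicated(vital$id)) stop("more than one vital record for a subject")
  last_age <- tapply(obs$age, obs$id, max)
  vd <- vital[!is.na(vital$death_age), ]
  if (nrow(vd)) {
    la <- last_age[as.character(vd$id)]
    bad <- !is.na(la) & vd$death_age < la
    if (any(bad)) {
      stop("death_age precedes the last observation for subject(s): ",
           paste(vd$id[bad], collapse = ", "))
    }
  }
  validation <- list(
    n_subjects = length(unique(obs$id)),
    n_observations = nrow(obs),
    n_deaths = sum(!is.na(vital$death_age)),
    n_under_age = sum(obs$age < 50),
    n_state_unknown = sum(obs$state == 0L)
  )
  structure(list(obs = obs, vital = vital, covariates = covariates,
                 validation = validation),
            class = "hwle_panel")
}

#' @export
print.hwle_panel <- function(x, ...) {
  v <- x$validation
  cat("hwle panel dataset\n")
  cat(sprintf("  subjects: %d  observations: %d  deaths: %d\n",
              v$n_subjects, v$n_observations, v$n_deaths))
  cat(sprintf("  state unknown: %d  under age 50: %d\n",
              v$n_state_unknown, v$n_under_age))
  cat("  covariates:", if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Validation summary of a panel dataset
#'
#' @param dataset an `hwle_panel`.
#' @return named list of counts (subjects, observations, deaths, unknown
#'   states, under-age records).
#' @export
validate_panel <- function(dataset) {
  stopifnot(inherits(dataset, "hwle_panel"))
  dataset$validation
}

#' Age at an event from birth year and event month/year
#'
#' Under the `midyear_birth` convention birth is placed at June of the birth
#' year, so age = (event_year - birth_year) + (event_month - 6)/12; under
#' `exact` the supplied birth month is used.
#'
#' @param birth_year integer year of birth.
#' @param event_month integer month (1-12) of the event.
#' @param event_year integer year of the event.
#' @param convention `"midyear_birth"` or `"exact"`.
#' @param birth_month integer month of birth (used by `"exact"` only).
#' @return age in years (fractional); negative ages are an error.
#' @examples
#' compute_age(1950, 6, 2000)   # 50
#' compute_age(1950, 12, 2000)  # 50.5
#' @export
compute_age <- function(birth_year, event_month, event_year,
                        convention = c("midyear_birth", "exact"),
                        birth_month = 6) {
  convention <- match.arg(convention)
  bm <- if (convention == "midyear_birth") 6 else birth_month
  age <- (event_year - birth_year) + (event_month - bm) / 12
  if (any(age < 0, na.rm = TRUE)) {
    stop("event date precedes birth date (negative age)")
  }
  age
}

#' Read a long-format panel CSV
#'
#' One row per subject-wave. The state can be supplied directly (`state`
#' column, codes 0:4) or derived from logical/0-1 `health` and `work`
#' columns via [classify_state()]. Ages can be supplied directly (`age`) or
#' derived from `birth_year` + `interview_month` + `interview_year` via
#' [compute_age()]. Death ages likewise come from a `death_age` column or
#' from `death_month`/`death_year`. Missing values are empty fields.
#'
#' @param path CSV file path.
#' @param schema named list mapping roles to column names. Recognised roles:
#'   `id`, `wave`, `age` *or* (`birth_year`, `interview_month`,
#'   `interview_year`), `state` *or* (`health`, `work`), `death_age` *or*
#'   (`death_month`, `death_year`), `followup_end_age`, `covariates`
#'   (character vector). Optional `age_convention` ("midyear_birth", the
#'   ELSA-like default, or "exact" for NorStOP-like data).
#' @return an `hwle_panel`.
#' @export
read_panel <- function(path, schema = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  get <- function(role, default = role) {
    col <- if (!is.null(schema[[role]])) schema[[role]] else default
    col
  }
  require_col <- function(col, role) {
    if (!col %in% names(raw)) {
      stop(sprintf("schema error: required column '%s' (role '%s') not found", col, role))
    }
    raw[[col]]
  }
  id <- require_col(get("id"), "id")
  wave <- require_col(get("wave"), "wave")
  convention <- if (!is.null(schema$age_convention)) schema$age_convention else "midyear_birth"

  if (get("age") %in% names(raw)) {
    age <- suppressWarnings(as.numeric(raw[[get("age")]]))
  } else {
    by <- require_col(get("birth_year"), "birth_year")
    im <- require_col(get("interview_month"), "interview_month")
    iy <- require_col(get("interview_year"), "interview_year")
    bm <- if (get("birth_month") %in% names(raw)) raw[[get("birth_month")]] else 6
    age <- compute_age(by, im, iy, convention = convention, birth_month = bm)
  }
  keep <- !is.na(age)
  n_dropped <- sum(!keep)
  if (n_dropped) message(n_dropped, " row(s) dropped: unparseable age")

  if (get("state") %in% names(raw)) {
    state <- as.integer(raw[[get("state")]])
    state[is.na(state)] <- 0L
  } else {
    health <- require_col(get("health"), "health")
    work <- require_col(get("work"), "work")
    state <- classify_state(.yn(health), .yn(work))
  }

  covariates <- if (!is.null(schema$covariates)) schema$covariates else character()
  for (cv in covariates) require_col(cv, paste0("covariate:", cv))

  obs <- data.frame(id = id, wave = wave, age = age, state = state,
                    stringsAsFactors = FALSE)
  for (cv in covariates) obs[[cv]] <- raw[[cv]]
  obs <- obs[keep, , drop = FALSE]

  # vital records: one per subject from the death / follow-up columns
  if (get("death_age") %in% names(raw)) {
    death_age <- suppressWarnings(as.numeric(raw[[get("death_age")]]))
  } else if (get("death_month") %in% names(raw) && get("death_year") %in% names(raw)) {
    dm <- suppressWarnings(as.numeric(raw[[get("death_month")]]))
    dy <- suppressWarnings(as.numeric(raw[[get("death_year")]]))
    by <- raw[[get("birth_year", "birth_year")]]
    death_age <- ifelse(is.na(dm) | is.na(dy), NA_real_,
                        compute_age(by, dm, dy, convention = convention))
  } else {
    death_age <- rep(NA_real_, nrow(raw))
  }
  fu <- if (get("followup_end_age") %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[get("followup_end_age")]]))
  } else rep(NA_real_, nrow(raw))
  vit <- data.frame(id = id, death_age = death_age, followup_end_age = fu,
                    stringsAsFactors = FALSE)
  vit <- vit[keep, , drop = FALSE]
  agg <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  vital <- do.call(rbind, lapply(split(vit, vit$id), function(d) {
    data.frame(id = d$id[1], death_age = agg(d$death_age),
               followup_end_age = agg(d$followup_end_age),
               stringsAsFactors = FALSE)
  }))
  rownames(vital) <- NULL
  panel_dataset(obs, vital, covariates = covariates)
}

#' Write a panel dataset as a long CSV
#'
#' Writes the `age` dialect of the long format (one row per subject-wave with
#' explicit fractional ages) together with the per-subject `death_age` and
#' `followup_end_age`, so that [read_panel()] reproduces the dataset exactly.
#'
#' @param dataset an `hwle_panel`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(dataset, path) {
  stopifnot(inherits(dataset, "hwle_panel"))
  obs <- dataset$obs
  vit <- dataset$vital
  m <- match(obs$id, vit$id)
  obs$death_age <- vit$death_age[m]
  obs$followup_end_age <- vit$followup_end_age[m]
  utils::write.csv(obs, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Extract interval-censored transition records
#'
#' Turns each trajectory into the records the likelihood consumes: one record
#' per consecutive observation pair (destination state 0 becomes an
#' `"unknown"` survival-only record), plus a terminal `"dead"` record from the
#' last interview to the month-precision death age for linked deaths.
#'
#' Mortality linkage determines vital status for every subject up to the
#' linkage end, so by default a subject alive at follow-up end contributes a
#' terminal survival-only (`"unknown"`) record from the last interview to
#' `followup_end_age`; without it, deaths occurring after study dropout would
#' enter the likelihood with no matching survivor exposure and mortality
#' would be overstated. Set `survivors = "last_interview"` to censor
#' survivors at their last interview instead.
#'
#' Records whose origin observation is missing a required covariate, has
#' unknown state, or lies below age 50 are kept but flagged `excluded` (with
#' the reason), so the bookkeeping identity
#' `nrow = sum(n_obs - 1) + n_deaths + n_extended` holds before exclusions.
#'
#' @param dataset an `hwle_panel`.
#' @param covariates covariate names required complete at the origin
#'   observation (default: the dataset's schema covariates are carried along
#'   but none are required).
#' @param survivors `"linkage_end"` (default: survival-only record to
#'   `followup_end_age`) or `"last_interview"` (censor there).
#' @return data.frame of records (`id`, `origin_state`, `origin_age`,
#'   `dest_kind` in live/dead/unknown, `dest_state`, `dest_age`, `excluded`,
#'   `exclude_reason`, covariate columns) with attributes `exclusions`
#'   (counts by reason) and `n_extended` (survivor records added).
#' @export
extract_transitions <- function(dataset, covariates = character(),
                                survivors = c("linkage_end", "last_interview")) {
  survivors <- match.arg(survivors)
  stopifnot(inherits(dataset, "hwle_panel"))
  obs <- dataset$obs
  vit <- dataset$vital
  carried <- dataset$covariates
  recs <- vector("list", length(unique(obs$id)))
  sp <- split(obs, obs$id)
  k <- 0L
  n_extended <- 0L
  for (d in sp) {
    k <- k + 1L
    n <- nrow(d)
    vrow <- match(d$id[1], vit$id)
    death_age <- vit$death_age[vrow]
    n_pairs <- if (n >= 2) n - 1L else 0L
    has_death <- length(death_age) == 1 && !is.na(death_age)
    fu_end <- vit$followup_end_age[vrow]
    extend <- survivors == "linkage_end" && !has_death &&
      length(fu_end) == 1 && !is.na(fu_end) && fu_end > d$age[n] + 1e-9
    n_extended <- n_extended + as.integer(extend)
    m <- n_pairs + as.integer(has_death) + as.integer(extend)
    if (m == 0L) next
    origin_idx <- c(if (n_pairs > 0) seq_len(n_pairs) else integer(),
                    if (has_death || extend) n)
    dest_state <- c(if (n_pairs > 0) d$state[2:n] else integer(),
                    if (has_death || extend) NA_integer_)
    dest_age <- c(if (n_pairs > 0) d$age[2:n] else numeric(),
                  if (has_death) death_age else if (extend) fu_end)
    kind <- c(if (n_pairs > 0) ifelse(d$state[2:n] == 0L, "unknown", "live") else character(),
              if (has_death) "dead" else if (extend) "unknown")
    r <- data.frame(id = d$id[1],
                    origin_state = d$state[origin_idx],
                    origin_age = d$age[origin_idx],
                    dest_kind = kind,
                    dest_state = ifelse(kind == "live", dest_state, NA_integer_),
                    dest_age = dest_age,
                    stringsAsFactors = FALSE)
    for (cv in carried) r[[cv]] <- d[[cv]][origin_idx]
    recs[[k]] <- r
  }
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(id = character(), origin_state = integer(),
                      origin_age = numeric(), dest_kind = character(),
                      dest_state = integer(), dest_age = numeric(),
                      excluded = logical(), exclude_reason = character(),
                      stringsAsFactors = FALSE)
    attr(out, "exclusions") <- c(missing_covariate = 0L, origin_unknown = 0L, under_age = 0L)
    attr(out, "n_extended") <- 0L
    return(out)
  }
  rownames(out) <- NULL
  reason <- rep(NA_character_, nrow(out))
  if (length(covariates)) {
    miss <- Reduce(`|`, lapply(covariates, function(cv) {
      if (!cv %in% names(out)) stop("required covariate not in dataset: ", cv)
      is.na(out[[cv]])
    }))
    reason[miss] <- "missing_covariate"
  }
  reason[out$origin_state == 0L] <- "origin_unknown"
  reason[out$origin_age < 50] <- "under_age"
  out$excluded <- !is.na(reason)
  out$exclude_reason <- reason
  attr(out, "exclusions") <- c(
    missing_covariate = sum(reason %in% "missing_covariate"),
    origin_unknown = sum(reason %in% "origin_unknown"),
    under_age = sum(reason %in% "under_age")
  )
  attr(out, "n_extended") <- n_extended
  out
}
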