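#' Classify health/work flags into a state code
#'
#' Maps tri-state healthy/working indicators onto the four live model states.
#' Either component missing yields state 0 ("alive, state unknown"): such
#' observations inform survival but not movement between live states.
#'
#' @param healthy logical vector (TRUE/FALSE/NA).
#' @param working logical vector (TRUE/FALSE/NA), recycled against `healthy`.
#' @return integer vector with values in 0:4 (1 = healthy & working,
#'   2 = healthy & not working, 3 = not healthy & working,
#'   4 = not healthy & not working, 0 = alive, state unknown).
#' @examples
#' classify_state(TRUE, TRUE)   # 1
#' classify_state(FALSE, FALSE) # 4
#' classify_state(NA, TRUE)     # 0
#' @export
classify_state <- function(healthy, working) {
  n <- max(length(healthy), length(working))
  healthy <- rep_len(as.logical(healthy), n)
  working <- rep_len(as.logical(working), n)
  out <- integer(n)
  known <- !is.na(healthy) & !is.na(working)
  out[known] <- ifelse(healthy[known],
                       ifelse(working[known], 1L, 2L),
                       ifelse(working[known], 3L, 4L))
  out
}

.yn <- function(x) {
  # normalise y/n/yes/no/TRUE/FALSE (and NA / "not_asked") to logical
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("y", "yes", "true", "1")] <- TRUE
  out[x %in% c("n", "no", "false", "0")] <- FALSE
  out
}

#' Derive the health flag from the two-item limiting illness questions
#'
#' A respondent is unhealthy only when a long-standing illness is reported
#' *and* reported to limit activities. The limiting item is only asked when
#' an illness is reported; an answer without a reported illness triggers a
#' validation warning and the illness item alone decides.
#'
#' @param longstanding_illness "y"/"n"/NA (or logical): any long-standing
#'   illness, disability or infirmity.
#' @param limits_activities "y"/"n"/"not_asked"/NA (or logical): whether the
#'   illness limits activities.
#' @return logical vector: TRUE = healthy, FALSE = not healthy, NA = unknown.
#' @export
derive_health_elsa <- function(longstanding_illness, limits_activities) {
  ill <- .yn(longstanding_illness)
  lim_raw <- limits_activities
  lim <- .yn(ifelse(tolower(as.character(lim_raw)) == "not_asked", NA, as.character(lim_raw)))
  n <- max(length(ill), length(lim))
  ill <- rep_len(ill, n); lim <- rep_len(lim, n)
  inconsistent <- !is.na(lim) & !is.na(ill) & !ill
  if (any(inconsistent)) {
    warning(sprintf("%d limiting-item answer(s) without a reported illness; using the illness item alone",
                    sum(inconsistent)))
  }
  out <- rep(NA, n)
  out[!is.na(ill) & !ill] <- TRUE                       # no illness
  out[!is.na(ill) & ill & !is.na(lim) & !lim] <- TRUE   # illness, not limiting
  out[!is.na(ill) & ill & !is.na(lim) & lim] <- FALSE   # limiting illness
  out
}

#' Derive the health flag from four activity-limitation sub-items
#'
#' Healthy means all four sub-items (two physical, two emotional) were
#' answered "no". Any "yes" marks the respondent not healthy; any unanswered
#' sub-item without a "yes" elsewhere leaves health missing, since a "yes"
#' cannot be ruled out.
#'
#' @param physical1,physical2 "y"/"n"/NA: limitation sub-items attributed to
#'   physical health.
#' @param emotional1,emotional2 "y"/"n"/NA: limitation sub-items attributed to
#'   emotional problems.
#' @return logical vector: TRUE = healthy, FALSE = not healthy, NA = unknown.
#' @export
derive_health_norstop <- function(physical1, physical2, emotional1, emotional2) {
  items <- lapply(list(physical1, physical2, emotional1, emotional2), .yn)
  n <- max(lengths(items))
  items <- lapply(items, rep_len, n)
  m <- do.call(cbind, items)
  any_yes <- apply(m, 1, function(r) any(r %in% TRUE))
  all_no <- apply(m, 1, function(r) all(!is.na(r)) && all(!r))
  out <- rep(NA, n)
  out[any_yes] <- FALSE
  out[all_no] <- TRUE
  out
}

#' Derive the working flag from the paid-work report
#'
#' @param work_report "in_paid_work" / "not_in_paid_work" / NA (or logical).
#' @return logical vector with missing passthrough.
#' @export
derive_work <- function(work_report) {
  if (is.logical(work_report)) return(work_report)
  x <- tolower(as.character(work_report))
  out <- rep(NA, length(x))
  out[x %in% c("in_paid_work", "y", "yes", "true", "1")] <- TRUE
  out[x %in% c("not_in_paid_work", "n", "no", "false", "0")] <- FALSE
  out
}

#' Resolve per-wave osteoarthritis self-reports
#'
#' Osteoarthritis is treated as irreversible once self-reported as doctor
#' diagnosed: a "yes" is carried forward to all later waves. A "no" is carried
#' backward into earlier missing values (a respondent without the condition
#' now never had it). A missing value strictly between a "no" and the first
#' "yes" stays missing. A "no" reported after a "yes" is overridden by the
#' forward-carried "yes" and counted as a conflict (attribute `"conflicts"`).
#'
#' @param reports wave-ordered vector of "yes"/"no"/NA (or logical).
#' @return logical vector of resolved per-wave status with attribute
#'   `conflicts` (number of overridden "no" reports).
#' @examples
#' propagate_oa(c(NA, FALSE, NA, TRUE, NA)) # F F NA T T
#' @export
propagate_oa <- function(reports) {
  v <- .yn(reports)
  n <- length(v)
  out <- v
  conflicts <- 0L
  first_yes <- which(v %in% TRUE)[1]
  if (!is.na(first_yes)) {
    later <- first_yes:n
    conflicts <- sum(out[later] %in% FALSE)
    out[later] <- TRUE
  }
  # carry "no" backward into earlier missing values
  if (n > 1) {
    for (i in (n - 1):1) {
      if (is.na(out[i]) && isFALSE(out[i + 1])) out[i] <- FALSE
    }
  }
  structure(out, conflicts = conflicts)
}

#' Assign a fixed occupation category from per-wave responses
#'
#' The earliest non-missing response applies to all waves; with no response at
#' any wave the category is `"unknown"`.
#'
#' @param responses wave-ordered character vector (e.g. "self_employed",
#'   "non_manual", "manual") with NA for missing.
#' @return single character value.
#' @export
assign_occupation <- function(responses) {
  x <- as.character(responses)
  first <- which(!is.na(x) & x != "")[1]
  if (is.na(first)) "unknown" else x[first]
}
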