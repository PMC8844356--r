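#' Build a single-year period life table from the panel
#'
#' Mortality is observed without classifying subjects into health or work
#' states: each subject contributes person-years of exposure from their first
#' observation to their death age (if linked) or their last observation
#' (censored alive), and a death at the age interval containing the
#' month-precision death age. Central rates `m_x = deaths / person_years`
#' convert to probabilities by the standard actuarial relation
#' `q_x = m_x / (1 + 0.5 m_x)` (mid-interval deaths, `a_x = 0.5` at all ages
#' over 50). Survivors `l_x` descend from a radix of 100000,
#' `L_x = l_(x+1) + 0.5 d_x`, and `e_x = sum_(y>=x) L_y / l_x`; the final
#' open interval is closed with `e_omega = 1 / m_omega`.
#'
#' Ages inside the range with no exposure borrow `q_x` from the nearest
#' estimated age, with a warning.
#'
#' @param dataset an `hwle_panel`.
#' @param age_range two ages bounding the table (default c(50, 110)).
#' @param survivors `"linkage_end"` (default: survivors contribute exposure
#'   to `followup_end_age`, since linkage establishes they were alive) or
#'   `"last_interview"`.
#' @return object of class `hwle_lifetable`: a data.frame with columns age,
#'   person_years, deaths, mx, qx, lx, dx, Lx, ex.
#' @export
build_lifetable <- function(dataset, age_range = c(50, 110),
                            survivors = c("linkage_end", "last_interview")) {
  stopifnot(inherits(dataset, "hwle_panel"), length(age_range) == 2)
  survivors <- match.arg(survivors)
  obs <- dataset$obs
  vit <- dataset$vital
  entry <- tapply(obs$age, obs$id, min)
  last <- tapply(obs$age, obs$id, max)
  ids <- names(entry)
  vi <- match(ids, vit$id)
  death <- vit$death_age[vi]
  alive_until <- last[ids]
  if (survivors == "linkage_end") {
    fu <- vit$followup_end_age[vi]
    alive_until <- ifelse(!is.na(fu), pmax(alive_until, fu), alive_until)
  }
  exit <- ifelse(is.na(death), alive_until, death)
  if (any(exit < entry)) stop("exit age precedes entry age")

  x <- seq(age_range[1], age_range[2] - 1)
  py <- numeric(length(x))
  dx_count <- numeric(length(x))
  for (i in seq_along(x)) {
    lo <- x[i]; hi <- x[i] + 1
    py[i] <- sum(pmax(0, pmin(exit, hi) - pmax(entry, lo)))
  }
  died <- !is.na(death)
  if (any(died)) {
    dage <- floor(death[died] - 1e-9)
    tab <- table(factor(dage, levels = x))
    dx_count <- as.numeric(tab)
  }

  # trim trailing ages with no exposure
  omega_i <- max(which(py > 0))
  x <- x[1:omega_i]; py <- py[1:omega_i]; dx_count <- dx_count[1:omega_i]

  mx <- ifelse(py > 0, dx_count / py, NA_real_)
  qx <- mx / (1 + 0.5 * mx)
  if (anyNA(qx)) {
    warning(sum(is.na(qx)), " age(s) with zero exposure; q carried from the nearest estimated age")
    known <- which(!is.na(qx))
    for (i in which(is.na(qx))) {
      qx[i] <- qx[known[which.min(abs(known - i))]]
    }
    mx[is.na(mx)] <- qx[is.na(mx)] / (1 - 0.5 * qx[is.na(mx)])
  }
  qx <- pmin(qx, 1)

  nx <- length(x)
  lx <- numeric(nx)
  lx[1] <- 1e5
  for (i in seq_len(nx - 1)) lx[i + 1] <- lx[i] * (1 - qx[i])
  dx <- lx * qx
  Lx <- numeric(nx)
  if (nx > 1) Lx[1:(nx - 1)] <- lx[2:nx] + 0.5 * dx[1:(nx - 1)]
  e_omega <- if (!is.na(mx[nx]) && mx[nx] > 0) 1 / mx[nx] else 0.5
  Lx[nx] <- lx[nx] * e_omega
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)

  structure(data.frame(age = x, person_years = py, deaths = dx_count,
                       mx = mx, qx = qx, lx = lx, dx = dx, Lx = Lx, ex = ex),
            class = c("hwle_lifetable", "data.frame"))
}

#' Remaining life expectancy at an age from a life table
#'
#' @param lifetable an `hwle_lifetable`.
#' @param age integer age within the table.
#' @return e_x in years.
#' @export
le_from <- function(lifetable, age) {
  stopifnot(inherits(lifetable, "hwle_lifetable"))
  i <- match(age, lifetable$age)
  if (is.na(i)) {
    stop(sprintf("age %s outside the life table range [%d, %d]",
                 format(age), min(lifetable$age), max(lifetable$age)))
  }
  lifetable$ex[i]
}
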