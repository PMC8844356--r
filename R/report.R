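#' Configuration for an end-to-end analysis run
#'
#' Exactly one of `simulation` / `input` must be supplied. In `"covariate"`
#' mode one model is fitted with the spec's covariate terms and expectancies
#' are reported per covariate profile; in `"stratified"` mode the data are
#' split on a fixed variable and independent models (without that term) are
#' fitted per stratum — the two designs used for time-dependent versus
#' fixed osteoarthritis status.
#'
#' @param simulation an `hwle_sim_config`, or NULL.
#' @param input list(path, schema) for [read_panel()], or NULL.
#' @param mode `"covariate"` or `"stratified"`.
#' @param strat_var stratification variable (stratified mode; default "oa").
#' @param spec analysis `hwle_spec`. Default: intercept + age + oa (covariate
#'   mode) or intercept + age (stratified mode), yearly steps.
#' @param index_ages ages at which expectancy tables are produced.
#' @param curve_ages ages for the HWLE-by-age table (default 50:75).
#' @param window prevalence window in years.
#' @param n_draws CI draws per expectancy table.
#' @param seed seed for the CI draws.
#' @param out_dir optional output directory for CSV tables, run log and
#'   machine-readable summary.
#' @return object of class `hwle_run_config`.
#' @export
run_config <- function(simulation = NULL, input = NULL,
                       mode = c("covariate", "stratified"),
                       strat_var = "oa", spec = NULL,
                       index_ages = c(50, 65), curve_ages = 50:75,
                       window = 5, n_draws = 1000, seed = 1L,
                       out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.null(simulation) == is.null(input)) {
    stop("exactly one of simulation / input must be supplied")
  }
  if (is.null(spec)) {
    spec <- if (mode == "covariate") model_spec(terms = c("intercept", "age", "oa"))
            else model_spec(terms = c("intercept", "age"))
  }
  if (mode == "stratified" && strat_var %in% spec$terms) {
    stop("stratified mode: the stratification variable must not be a model term")
  }
  structure(list(simulation = simulation, input = input, mode = mode,
                 strat_var = strat_var, spec = spec,
                 index_ages = index_ages, curve_ages = curve_ages,
                 window = window, n_draws = n_draws, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "hwle_run_config")
}

# subset a panel to subjects whose first non-missing value of `var` equals v
.stratum_panel <- function(dataset, var, v) {
  obs <- dataset$obs
  firstval <- tapply(obs[[var]], obs$id, function(x) x[which(!is.na(x))[1]])
  ids <- names(firstval)[!is.na(firstval) & firstval == v]
  keep <- obs$id %in% ids
  panel_dataset(obs[keep, , drop = FALSE],
                dataset$vital[dataset$vital$id %in% ids, , drop = FALSE],
                covariates = dataset$covariates)
}

#' Run the full analysis pipeline
#'
#' Simulate (or read), fit, and convert to expectancies: per profile or
#' stratum and index age, the four state expectancies with CIs and LE; HWLE
#' by age over `curve_ages`; HWLE as a percentage of LE; and the life-table
#' LE computed from the same panel as a mortality cross-check. A timestamped
#' run log records seeds, exclusion counts and convergence diagnostics.
#' Reruns with an identical configuration are byte-identical.
#'
#' @param config an `hwle_run_config`.
#' @return object of class `hwle_report`: list with `tables` (long
#'   data.frame), `curve`, `pct_of_le`, `lifetable_le`, `fits`, `truth`
#'   (when simulated), `log`, `config`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "hwle_run_config"))
  log <- character()
  note <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), sprintf(fmt, ...))
    log <<- c(log, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  truth <- NULL
  dataset <- stage("data", {
    if (!is.null(config$simulation)) {
      note("simulating cohort: preset=%s n=%d seed=%d", config$simulation$preset,
           config$simulation$n_subjects, config$simulation$seed)
      gen <- generate_cohort(config$simulation)
      truth <- gen$truth
      gen$dataset
    } else {
      note("reading panel from %s", config$input$path)
      do.call(read_panel, config$input)
    }
  })
  v <- dataset$validation
  note("panel: %d subjects, %d observations, %d deaths, %d unknown states",
       v$n_subjects, v$n_observations, v$n_deaths, v$n_state_unknown)

  spec <- config$spec
  fits <- stage("fit", {
    if (config$mode == "covariate") {
      f <- fit_mle(dataset, spec)
      list(model = f)
    } else {
      obs <- dataset$obs
      vals <- sort(unique(stats::na.omit(
        unlist(tapply(obs[[config$strat_var]], obs$id,
                      function(x) x[which(!is.na(x))[1]], simplify = FALSE)))))
      out <- list()
      for (v0 in vals) {
        out[[paste0(config$strat_var, "=", v0)]] <-
          fit_mle(.stratum_panel(dataset, config$strat_var, v0), spec)
      }
      out
    }
  })
  for (nm in names(fits)) {
    f <- fits[[nm]]
    note("fit %s: loglik=%.3f, records=%d, grad_norm=%.3g, frozen=%d",
         nm, f$loglik, f$n_used, f$diagnostics$grad_norm, nrow(f$frozen))
    ex <- f$exclusions
    if (!is.null(ex)) note("fit %s exclusions: %s", nm,
                           paste(names(ex), ex, sep = "=", collapse = ", "))
  }

  # analysis units: (label, fit, profile, stratum dataset for prevalence)
  units <- if (config$mode == "covariate") {
    covs <- spec$covariates
    if (length(covs)) {
      grid <- expand.grid(rep(list(0:1), length(covs)))
      names(grid) <- covs
      lapply(seq_len(nrow(grid)), function(i) {
        prof <- as.list(grid[i, , drop = FALSE])
        label <- paste(names(prof), unlist(prof), sep = "=", collapse = ",")
        list(label = label, fit = fits$model, profile = prof, data = dataset)
      })
    } else {
      list(list(label = "all", fit = fits$model, profile = NULL, data = dataset))
    }
  } else {
    lapply(names(fits), function(nm) {
      v0 <- as.numeric(sub(".*=", "", nm))
      list(label = nm, fit = fits[[nm]], profile = NULL,
           data = .stratum_panel(dataset, config$strat_var, v0))
    })
  }

  tables <- list()
  pct <- list()
  for (u in units) {
    for (a in config$index_ages) {
      et <- stage("expectancies", tryCatch(
        expectancy_table(u$fit, dataset = u$data, profile = u$profile,
                         start_age = a, window = config$window,
                         n_draws = config$n_draws, seed = config$seed),
        error = function(e) NULL))
      if (is.null(et)) {
        note("expectancies skipped for %s at age %s (no prevalence support)", u$label, a)
        next
      }
      row <- data.frame(profile = u$label, start_age = a,
                        quantity = c("hwle", "e2", "e3", "e4", "le"),
                        estimate = c(et$weighted, et$le),
                        stringsAsFactors = FALSE)
      if (!is.null(et$ci)) {
        row$lower <- et$ci$lower; row$upper <- et$ci$upper
      }
      tables[[length(tables) + 1L]] <- row
      pct[[length(pct) + 1L]] <- data.frame(
        profile = u$label, start_age = a,
        hwle = et$weighted[1], le = et$le,
        pct_of_le = percent_of_le(et$weighted[1], et$le),
        stringsAsFactors = FALSE)
    }
  }
  tables <- do.call(rbind, tables)
  pct <- do.call(rbind, pct)
  rownames(tables) <- rownames(pct) <- NULL

  curve <- stage("curve", {
    do.call(rbind, lapply(units, function(u) {
      profs <- list(u$profile); names(profs) <- u$label
      hwle_curve(u$fit, u$data, profiles = profs, ages = config$curve_ages,
                 window = config$window)
    }))
  })

  lt <- stage("lifetable", build_lifetable(dataset))
  lt_le <- le_from(lt, min(config$index_ages))
  note("life-table LE at %d: %.3f years", min(config$index_ages), lt_le)

  report <- structure(list(tables = tables, curve = curve, pct_of_le = pct,
                           lifetable = lt, lifetable_le = lt_le,
                           fits = fits, truth = truth, log = log,
                           config = config),
                      class = "hwle_report")
  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

# serialisation boundary: tables rounded to 2 dp, checks stay full precision
.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rounded <- report$tables
  for (cl in intersect(c("estimate", "lower", "upper"), names(rounded))) {
    rounded[[cl]] <- round(rounded[[cl]], 2)
  }
  utils::write.csv(rounded, file.path(out_dir, "expectancy_tables.csv"), row.names = FALSE)
  crv <- report$curve
  crv$hwle <- round(crv$hwle, 2); crv$le <- round(crv$le, 2)
  utils::write.csv(crv, file.path(out_dir, "hwle_curve.csv"), row.names = FALSE)
  utils::write.csv(report$pct_of_le, file.path(out_dir, "pct_of_le.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$lifetable), file.path(out_dir, "lifetable.csv"),
                   row.names = FALSE)
  for (nm in names(report$fits)) {
    utils::write.csv(report$fits[[nm]]$par,
                     file.path(out_dir, paste0("coefficients_", gsub("[^A-Za-z0-9]", "_", nm), ".csv")),
                     row.names = FALSE)
  }
  writeLines(report$log, file.path(out_dir, "run.log"))
  cfg <- report$config
  summary <- list(
    mode = cfg$mode, seed = cfg$seed, n_draws = cfg$n_draws,
    index_ages = cfg$index_ages,
    loglik = lapply(report$fits, function(f) f$loglik),
    n_records = lapply(report$fits, function(f) f$n_used),
    grad_norm = lapply(report$fits, function(f) f$diagnostics$grad_norm),
    lifetable_le = report$lifetable_le
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.hwle_report <- function(x, ...) {
  cat("hwle analysis report (", x$config$mode, " mode)\n", sep = "")
  print(x$pct_of_le, digits = 4)
  cat(sprintf("life-table LE at %d: %.2f years\n",
              min(x$config$index_ages), x$lifetable_le))
  invisible(x)
}

#' Internal-consistency checks on a report
#'
#' For every profile/age: the four state expectancies must sum to LE within
#' `tol` years before rounding; HWLE must not exceed LE; and each CI must
#' contain its point estimate. Checks run on full precision. Failures are
#' listed, not raised.
#'
#' @param x an `hwle_report`, or a data.frame with columns `hwle`, `e2`,
#'   `e3`, `e4`, `le` (one row per group) for checking externally supplied
#'   tables.
#' @param tol sum-to-LE tolerance in years (default 0.005).
#' @return data.frame of checks with columns `group`, `check`, `pass`,
#'   `detail`; attribute `pass` is the conjunction.
#' @export
consistency_check <- function(x, tol = 0.005) {
  rows <- list()
  add <- function(group, check, pass, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(group = group, check = check,
                                             pass = pass, detail = detail,
                                             stringsAsFactors = FALSE)
  }
  if (inherits(x, "hwle_report")) {
    tab <- x$tables
    for (key in unique(paste(tab$profile, tab$start_age, sep = " @"))) {
      sub <- tab[paste(tab$profile, tab$start_age, sep = " @") == key, ]
      est <- setNames(sub$estimate, sub$quantity)
      gap <- abs(sum(est[c("hwle", "e2", "e3", "e4")]) - est["le"])
      add(key, "sum_to_le", gap <= tol, sprintf("gap=%.6f", gap))
      add(key, "hwle_le_le", est["hwle"] <= est["le"] + 1e-12, "")
      if (!is.null(sub$lower)) {
        ok <- all(sub$lower <= sub$estimate + 1e-9 & sub$estimate <= sub$upper + 1e-9)
        add(key, "ci_contains_point", ok, "")
      }
      add(key, "finite", all(is.finite(est)), "")
    }
  } else {
    stopifnot(is.data.frame(x), all(c("hwle", "e2", "e3", "e4", "le") %in% names(x)))
    for (i in seq_len(nrow(x))) {
      gap <- abs(x$hwle[i] + x$e2[i] + x$e3[i] + x$e4[i] - x$le[i])
      add(paste0("row", i), "sum_to_le", gap <= tol, sprintf("gap=%.6f", gap))
      add(paste0("row", i), "hwle_le_le", x$hwle[i] <= x$le[i] + 1e-12, "")
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pass") <- all(out$pass)
  out
}
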