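# Null calibration with pseudo-outcomes and the sensitivity-scenario
# grid (age range, AB cap, incidence gap, subclass instruments,
# inverse-normal transform, sex strata).

#' Generate instrument-independent pseudo-outcomes
#'
#' Creates one binary pseudo-disease per target probability by
#' independent Bernoulli draws, unrelated to any exposure by
#' construction.  The default grid 2.5%, 5%, ..., 97.5% yields 39
#' pseudo-variables.  Used to check that the estimator declares no more
#' than the nominal share of significant associations when none exist.
#'
#' @param person_ids identifiers of the outcome-cohort subjects.
#' @param probabilities target prevalences, strictly inside (0, 1).
#' @param seed optional RNG seed for reproducibility.
#' @param followup_start,followup_end window used for the (arbitrary)
#'   incident dates attached to cases.
#' @return an `abivr_outcomes` table with one pseudo-disease per
#'   probability; incident cases get a uniform date in the follow-up
#'   window, non-cases are `censored_nonevent`.
#' @export
make_pseudo_outcomes <- function(person_ids,
                                 probabilities = seq(0.025, 0.975, by = 0.025),
                                 seed = NULL,
                                 followup_start = as.Date("2015-01-01"),
                                 followup_end = as.Date("2022-12-31")) {
  if (any(probabilities <= 0 | probabilities >= 1)) {
    stop("probabilities must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  ids <- as.character(person_ids)
  n <- length(ids)
  span <- as.integer(followup_end - followup_start)
  res <- vector("list", length(probabilities))
  for (k in seq_along(probabilities)) {
    case <- stats::runif(n) < probabilities[k]
    first <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
    first[case] <- followup_start + 1L +
      floor(stats::runif(sum(case)) * span)
    res[[k]] <- data.frame(
      person_id = ids,
      disease = sprintf("pseudo_%04.1f", 100 * probabilities[k]),
      status = ifelse(case, "incident", "censored_nonevent"),
      first_date = first,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$status <- factor(out$status,
                       levels = c("incident", "prevalent_excluded",
                                  "censored_nonevent"))
  rownames(out) <- NULL
  attr(out, "probabilities") <- probabilities
  class(out) <- c("abivr_outcomes", "data.frame")
  out
}

#' Null calibration of the disease panel
#'
#' Replaces the real outcomes with instrument-independent pseudo-diseases
#' and runs the full panel.  Under a valid estimator the proportion of
#' nominally significant estimates should stay near the alpha level and
#' the FDR-adjusted proportion at or below it (expected: zero).
#'
#' @param sample1,sample2 cohort inputs as for [abivr()]; `sample1` may
#'   be an `abivr_simdata` object.
#' @param probabilities pseudo-disease prevalences (default: 39 values,
#'   2.5% to 97.5%).
#' @param seed RNG seed for the pseudo-outcome draws.
#' @param alpha significance level (default 0.05).
#' @param ... further settings passed to [abivr()] (instrument, filters,
#'   `min_cases`, ...).
#' @return object of class `abivr_calibration`: counts and proportions
#'   of FDR- and nominally-significant pseudo-diseases, the panel
#'   estimates, and `pass` (`proportion_significant_fdr <= alpha`).
#' @export
null_calibration <- function(sample1, sample2 = NULL,
                             probabilities = seq(0.025, 0.975, by = 0.025),
                             seed = 1, alpha = 0.05, ...) {
  if (inherits(sample1, "abivr_simdata")) {
    sample2 <- sample1$sample2
    sample1 <- sample1$sample1
  }
  pseudo <- make_pseudo_outcomes(sample1$subjects$person_id,
                                 probabilities = probabilities, seed = seed)
  fit <- abivr(sample1, sample2, outcomes = pseudo, ...)
  est <- fit$estimates
  ok <- est$status == "ok"
  n_eval <- sum(ok)
  n_fdr <- sum(est$p_fdr[ok] <= alpha, na.rm = TRUE)
  n_nom <- sum(est$p[ok] <= alpha, na.rm = TRUE)
  structure(list(
    n_pseudo = length(probabilities),
    probabilities = probabilities,
    n_evaluated = n_eval,
    n_significant_fdr = n_fdr,
    n_significant_nominal = n_nom,
    proportion_significant_fdr = if (n_eval) n_fdr / n_eval else NA_real_,
    proportion_significant_nominal = if (n_eval) n_nom / n_eval else NA_real_,
    alpha = alpha, seed = seed, pass = n_eval > 0 && n_fdr / n_eval <= alpha,
    estimates = est, fit = fit
  ), class = "abivr_calibration")
}

#' @export
print.abivr_calibration <- function(x, ...) {
  cat("Pseudo-outcome null calibration\n")
  cat(sprintf("  %d pseudo-diseases (prevalences %.1f%%-%.1f%%), %d evaluated\n",
              x$n_pseudo, 100 * min(x$probabilities),
              100 * max(x$probabilities), x$n_evaluated))
  cat(sprintf("  FDR-significant (alpha = %.2g): %d (%.1f%%)\n",
              x$alpha, x$n_significant_fdr,
              100 * x$proportion_significant_fdr))
  cat(sprintf("  nominally significant: %d (%.1f%%)\n",
              x$n_significant_nominal,
              100 * x$proportion_significant_nominal))
  cat(sprintf("  calibration %s\n", if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Default sensitivity-scenario grid
#'
#' The standard robustness suite: the main analysis (ages 23-50, cap 5),
#' widened age range (23-89), widened AB cap (10), a 5-year incidence
#' gap, each antibiotic subclass as the instrument, the inverse-normal
#' transformed exposure, and sex strata (the male stratum also widens
#' the age range, since the main settings leave few men).
#'
#' @return data frame of scenario specifications, one row per scenario.
#' @export
default_scenarios <- function() {
  spec <- function(name, min_age = 23, max_age = 50, max_ab = 5,
                   gap_years = 0, instrument = "total", transform = "none",
                   sex = "all") {
    data.frame(name = name, min_age = min_age, max_age = max_age,
               max_ab = max_ab, gap_years = gap_years,
               instrument = instrument, transform = transform, sex = sex,
               stringsAsFactors = FALSE)
  }
  rbind(
    spec("main"),
    spec("age_23_89", max_age = 89),
    spec("ab_cap_10", max_ab = 10),
    spec("gap_5y", gap_years = 5),
    spec("instr_J01CR", instrument = "J01CR"),
    spec("instr_J01FA", instrument = "J01FA"),
    spec("instr_J01MA", instrument = "J01MA"),
    spec("int_transform", transform = "int"),
    spec("female", sex = "female"),
    spec("male_23_89", max_age = 89, sex = "male")
  )
}

#' Run the sensitivity-scenario grid
#'
#' Rebuilds the cohorts and reruns the disease panel under each scenario
#' specification, returning one tidy row per disease and scenario.
#' Scenarios that empty the analysis set (or otherwise fail) are
#' reported as skipped rather than aborting the grid.
#'
#' @param sample1,sample2 cohort inputs as for [abivr()]; `sample1` may
#'   be an `abivr_simdata` object (its disease definitions are then
#'   used).
#' @param icd_codes named list of ICD-10 prefixes per disease.
#' @param scenarios data frame as from [default_scenarios()].
#' @param ... further shared settings passed to [abivr()] (e.g.
#'   `min_cases`).
#' @return data frame of class `abivr_sensitivity`: panel estimates with
#'   a leading `scenario` column; skipped scenarios appear with
#'   `status = "skipped_scenario"`.
#' @export
run_sensitivity_grid <- function(sample1, sample2 = NULL, icd_codes = NULL,
                                 scenarios = default_scenarios(), ...) {
  if (inherits(sample1, "abivr_simdata")) {
    if (is.null(icd_codes)) icd_codes <- scenario_icd_codes(sample1$scenario)
    sample2 <- sample1$sample2
    sample1 <- sample1$sample1
  }
  stopifnot(is.data.frame(scenarios), nrow(scenarios) > 0)
  rows <- vector("list", nrow(scenarios))
  for (k in seq_len(nrow(scenarios))) {
    sp <- scenarios[k, ]
    fit <- tryCatch(
      suppressWarnings(abivr(
        sample1, sample2, icd_codes = icd_codes,
        instrument = sp$instrument, min_age = sp$min_age,
        max_age = sp$max_age, max_ab = sp$max_ab,
        gap_years = sp$gap_years, transform = sp$transform, sex = sp$sex,
        ...)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[k]] <- data.frame(scenario = sp$name, disease = NA_character_,
                              status = "skipped_scenario",
                              reason = conditionMessage(fit),
                              stringsAsFactors = FALSE)
    } else {
      est <- fit$estimates
      est <- cbind(scenario = sp$name, est, reason = NA_character_,
                   stringsAsFactors = FALSE)
      rows[[k]] <- est
    }
  }
  # align columns across successful and skipped scenarios
  cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(cols, names(r))) r[[cc]] <- NA
    r[cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("abivr_sensitivity", "data.frame")
  out
}

#' Write a sensitivity/calibration report
#'
#' Writes the tidy scenario results as TSV, the calibration summary as
#' TSV (or a note that calibration was skipped), and a forest-style SVG
#' figure of the causal estimates with confidence intervals per
#' scenario.  Output is deterministic for fixed inputs.
#'
#' @param results a table from [run_sensitivity_grid()] (or an `abivr`
#'   fit's `estimates`, with or without a `scenario` column).
#' @param calibration optional `abivr_calibration` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(results, calibration = NULL, dir) {
  if (is.null(results) || nrow(as.data.frame(results)) == 0L) {
    stop("results must be non-empty", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- as.data.frame(results)
  paths <- character(0)

  p_res <- file.path(dir, "sensitivity_results.tsv")
  utils::write.table(res, p_res, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p_res)

  p_cal <- file.path(dir, "calibration.tsv")
  if (is.null(calibration)) {
    writeLines("calibration skipped", p_cal)
  } else {
    cal <- data.frame(
      n_pseudo = calibration$n_pseudo,
      n_evaluated = calibration$n_evaluated,
      n_significant_fdr = calibration$n_significant_fdr,
      n_significant_nominal = calibration$n_significant_nominal,
      proportion_significant_fdr = calibration$proportion_significant_fdr,
      proportion_significant_nominal =
        calibration$proportion_significant_nominal,
      alpha = calibration$alpha, seed = calibration$seed,
      pass = calibration$pass)
    utils::write.table(cal, p_cal, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  paths <- c(paths, p_cal)

  ok <- !is.na(res$status) & res$status == "ok"
  p_fig <- file.path(dir, "forest.svg")
  if (any(ok)) {
    est <- res[ok, , drop = FALSE]
    grp <- if ("scenario" %in% names(est)) est$scenario else NULL
    lab <- if (is.null(grp)) est$disease else
      paste(est$disease, est$scenario, sep = " / ")
    grDevices::svg(p_fig, width = 7,
                   height = max(3, 0.28 * length(lab) + 1.5))
    forest_panel(lab, est$beta_d_mb, est$ci_low, est$ci_high,
                 sig = !is.na(est$p_fdr) & est$p_fdr <= 0.05, group = grp)
    grDevices::dev.off()
    paths <- c(paths, p_fig)
  }
  invisible(paths)
}
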