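# The user-facing model fit: antibiotic-history instrumental-variable
# regression across a disease panel, returning a classed object with the
# usual print/summary/coef/confint/plot methods.

# Build, filter and join the per-sample inputs shared by abivr(),
# null_calibration() and the sensitivity grid.
prepare_samples <- function(sample1, sample2, instrument, min_age, max_age,
                            max_ab, sex, transform, followup_start,
                            years_back = 10, washout_months = 6) {
  idx1 <- if (!is.null(sample1$index_date)) sample1$index_date else followup_start
  e1 <- build_exposure_table(sample1$prescriptions, sample1$subjects, idx1,
                             years_back = years_back,
                             washout_months = washout_months)
  if (is.null(sample2$index_dates)) {
    stop("sample2 needs per-person index_dates (person_id, index_date)",
         call. = FALSE)
  }
  e2 <- build_exposure_table(sample2$prescriptions, sample2$subjects,
                             sample2$index_dates,
                             years_back = years_back,
                             washout_months = washout_months)
  f1 <- filter_analysis_set(e1, min_age = min_age, max_age = max_age,
                            max_ab = max_ab, instrument = instrument,
                            sex = sex)
  f2 <- filter_analysis_set(e2, min_age = min_age, max_age = max_age,
                            max_ab = max_ab, instrument = instrument,
                            sex = sex)
  mb <- compute_log_pb(sample2$genus, int = identical(transform, "int"))
  list(exposure_s1 = f1, exposure_s2 = f2, mb = mb)
}

#' Fit the antibiotic-history IV regression across a disease panel
#'
#' Runs the full two-sample two-stage pipeline: builds per-person
#' antibiotic exposure tables for both samples (10-year window, 6-month
#' washout), applies the analysis-set filters (ages 23-50 and at most 5
#' courses by default), computes the log Prevotella/Bacteroides ratio in
#' the microbiome sample, defines incident-disease outcomes in the
#' outcome sample, and estimates the causal effect of log P/B on each
#' disease as the ratio of the stage-2 logistic and stage-1 linear
#' instrument coefficients, with delta-method standard errors and
#' Benjamini-Hochberg FDR across the panel.
#'
#' @param sample1 outcome cohort: either an `abivr_simdata` object from
#'   [simulate_two_samples()] (in which case `sample2` and `icd_codes`
#'   are taken from it) or a list with `subjects`, `prescriptions`,
#'   `diagnoses` and optionally `index_date`.
#' @param sample2 microbiome cohort: list with `subjects`,
#'   `prescriptions`, `genus` and `index_dates` (per-person sampling
#'   dates).
#' @param icd_codes named list of ICD-10 prefixes per disease; not
#'   needed when `outcomes` is supplied.
#' @param outcomes optional prebuilt outcomes table (overrides
#'   `icd_codes`), e.g. from [make_pseudo_outcomes()].
#' @param instrument `"total"` (all J01*), `"J01CR"`, `"J01FA"` or
#'   `"J01MA"`.
#' @param min_age,max_age,max_ab analysis-set filters (defaults 23, 50,
#'   5; sensitivity settings widen to 89 and 10).
#' @param gap_years treat the first `gap_years` of follow-up as
#'   prevalent (default 0; the feedback-loop sensitivity uses 5).
#' @param transform `"none"` or `"int"` (inverse-normal transform of
#'   log P/B before stage 1).
#' @param sex `"all"`, `"female"` or `"male"`.
#' @param min_cases minimum incident cases per disease (default 50).
#' @param covariates optional exposure-table columns to adjust both
#'   stages for.
#' @param fdr_threshold FDR significance threshold reported by
#'   `print`/`summary` (default 0.05; 0.1 is a common looser choice).
#' @param followup_start,followup_end follow-up window for incident
#'   outcomes.
#' @param ci_multiplier CI half-width in standard errors (default 1.96).
#' @return object of class `abivr`: list with `estimates` (one row per
#'   disease), `stage1`, `settings`, sample sizes and the call.
#' @examples
#' sim <- simulate_two_samples(sim_scenario(n_sample1 = 4000,
#'                                          n_sample2 = 600, seed = 7))
#' fit <- abivr(sim, min_cases = 20)
#' fit
#' coef(fit)
#' @export
abivr <- function(sample1, sample2 = NULL, icd_codes = NULL, outcomes = NULL,
                  instrument = "total", min_age = 23, max_age = 50,
                  max_ab = 5, gap_years = 0,
                  transform = c("none", "int"),
                  sex = c("all", "female", "male"),
                  min_cases = 50, covariates = NULL, fdr_threshold = 0.05,
                  followup_start = as.Date("2015-01-01"),
                  followup_end = as.Date("2022-12-31"),
                  ci_multiplier = 1.96) {
  transform <- match.arg(transform)
  sex <- match.arg(sex)
  cl <- match.call()
  if (inherits(sample1, "abivr_simdata")) {
    sim <- sample1
    if (is.null(icd_codes)) icd_codes <- scenario_icd_codes(sim$scenario)
    sample2 <- sim$sample2
    sample1 <- sim$sample1
  }
  prep <- prepare_samples(sample1, sample2, instrument, min_age, max_age,
                          max_ab, sex, transform, followup_start)
  if (is.null(outcomes)) {
    if (is.null(icd_codes)) {
      stop("supply either icd_codes or a prebuilt outcomes table",
           call. = FALSE)
    }
    outcomes <- define_incident_outcomes(sample1$diagnoses, sample1$subjects,
                                         icd_codes,
                                         followup_start = followup_start,
                                         followup_end = followup_end,
                                         gap_years = gap_years)
  }
  diseases <- unique(as.character(outcomes$disease))
  estimates <- run_disease_panel(prep$mb, prep$exposure_s2, prep$exposure_s1,
                                 outcomes, diseases,
                                 instrument = instrument,
                                 min_cases = min_cases,
                                 covariates = covariates,
                                 transform = transform,
                                 ci_multiplier = ci_multiplier)
  stage1 <- attr(estimates, "stage1")
  attr(estimates, "stage1") <- NULL
  structure(list(
    estimates = estimates,
    stage1 = stage1,
    settings = list(instrument = instrument, min_age = min_age,
                    max_age = max_age, max_ab = max_ab,
                    gap_years = gap_years, transform = transform, sex = sex,
                    min_cases = min_cases, fdr_threshold = fdr_threshold,
                    followup_start = followup_start,
                    followup_end = followup_end,
                    ci_multiplier = ci_multiplier),
    n_sample1 = nrow(prep$exposure_s1),
    n_sample2 = nrow(prep$exposure_s2),
    call = cl
  ), class = "abivr")
}

#' @export
print.abivr <- function(x, ...) {
  s <- x$settings
  cat("Antibiotic-history IV regression (two-sample ratio estimator)\n")
  cat(sprintf("  instrument: %s AB count; ages %g-%g; cap %g; sex: %s%s%s\n",
              s$instrument, s$min_age, s$max_age, s$max_ab, s$sex,
              if (s$gap_years > 0) sprintf("; %g-year incidence gap",
                                           s$gap_years) else "",
              if (s$transform == "int") "; INT exposure" else ""))
  cat(sprintf("  analysis sets: %d (outcome sample), %d (microbiome sample)\n",
              x$n_sample1, x$n_sample2))
  cat(sprintf("  stage 1: beta_MB,hAB = %.4f (SE %.4f)\n",
              x$stage1$beta, x$stage1$se))
  est <- x$estimates
  ok <- est$status == "ok"
  cat(sprintf("  panel: %d diseases (%d estimated, %d skipped); %d FDR-significant at %.2g\n",
              nrow(est), sum(ok), sum(!ok),
              sum(est$p_fdr[ok] <= s$fdr_threshold, na.rm = TRUE),
              s$fdr_threshold))
  cat("\nUse summary() for the full panel table.\n")
  invisible(x)
}

#' @export
summary.abivr <- function(object, ...) {
  structure(list(fit = object), class = "summary.abivr")
}

#' @export
print.summary.abivr <- function(x, digits = 4, ...) {
  fit <- x$fit
  print(fit)
  est <- fit$estimates
  cols <- c("disease", "n_cases", "beta_d_mb", "se_d_mb", "z", "p", "p_fdr",
            "ci_low", "ci_high", "status")
  tab <- est[cols]
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) signif(v, digits))
  cat("\n")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.abivr <- function(object, ...) {
  est <- object$estimates
  stats::setNames(est$beta_d_mb, est$disease)
}

#' @export
confint.abivr <- function(object, parm, level = 0.95, ...) {
  est <- object$estimates
  q <- stats::qnorm((1 + level) / 2)
  out <- cbind(est$beta_d_mb - q * est$se_d_mb,
               est$beta_d_mb + q * est$se_d_mb)
  rownames(out) <- est$disease
  colnames(out) <- paste0(format(100 * c((1 - level) / 2, (1 + level) / 2),
                                 trim = TRUE), " %")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Forest plot of causal estimates
#'
#' Draws the per-disease causal effect of log P/B with confidence
#' intervals, the standard display for an IV disease panel.
#'
#' @param x an `abivr` fit.
#' @param order_by `"estimate"` (default) or `"disease"` row ordering.
#' @param ... passed to [graphics::plot()].
#' @export
plot.abivr <- function(x, order_by = c("estimate", "disease"), ...) {
  order_by <- match.arg(order_by)
  est <- x$estimates[x$estimates$status == "ok", , drop = FALSE]
  if (nrow(est) == 0L) stop("no estimated diseases to plot", call. = FALSE)
  ord <- if (order_by == "estimate") order(est$beta_d_mb) else
    order(est$disease, decreasing = TRUE)
  est <- est[ord, , drop = FALSE]
  forest_panel(est$disease, est$beta_d_mb, est$ci_low, est$ci_high,
               sig = !is.na(est$p_fdr) &
                 est$p_fdr <= x$settings$fdr_threshold, ...)
  invisible(x)
}

# shared base-graphics forest renderer
forest_panel <- function(labels, beta, lo, hi, sig = NULL, group = NULL,
                         main = "Causal effect of log P/B ratio", ...) {
  n <- length(labels)
  y <- seq_len(n)
  xlim <- range(c(lo, hi, 0), finite = TRUE)
  op <- graphics::par(mar = c(4.5, 10, 3, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = expression(hat(beta)["D,MB"] ~ "(log-odds per unit log P/B)"),
                 ylab = "", main = main, ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  col <- if (is.null(group)) rep("black", n) else
    grDevices::hcl.colors(length(unique(group)), "Dark 3")[as.integer(factor(group))]
  graphics::segments(lo, y, hi, y, col = col)
  pch <- if (is.null(sig)) rep(16, n) else ifelse(sig, 17, 16)
  graphics::points(beta, y, pch = pch, col = col)
  graphics::axis(2, at = y, labels = labels, las = 1, cex.axis = 0.8)
  if (!is.null(group)) {
    graphics::legend("topright", legend = unique(group),
                     col = grDevices::hcl.colors(length(unique(group)),
                                                 "Dark 3"),
                     lty = 1, cex = 0.7, bty = "n")
  }
  invisible(NULL)
}
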