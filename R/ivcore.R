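# Two-sample two-stage least squares (TSTSLS) core.
#
# Stage 1: linear regression of the microbiome exposure (log P/B) on the
# antibiotic count in the microbiome cohort (sample 2).
# Stage 2: logistic regression of incident disease on the antibiotic
# count in the outcome cohort (sample 1).
# Causal estimate: ratio of coefficients beta_D,MB = beta_D,hAB /
# beta_MB,hAB with a delta-method (Pacini-Windmeijer) standard error,
# Wald z inference and Benjamini-Hochberg FDR across the disease panel.

#' Stage 1: regress the microbiome exposure on the instrument
#'
#' Ordinary least squares of `log_pb` on the chosen antibiotic count in
#' the microbiome cohort.  Optional covariates enter additively.  A
#' weak-instrument warning is emitted when the slope is less than
#' `weak_z` standard errors from zero.
#'
#' @param mb microbiome feature table from [compute_log_pb()] (columns
#'   `person_id`, `log_pb`, optionally `log_pb_int`).
#' @param exposure exposure table from [build_exposure_table()],
#'   typically already filtered with [filter_analysis_set()].
#' @param instrument `"total"`, `"J01CR"`, `"J01FA"` or `"J01MA"`.
#' @param covariates optional character vector of exposure-table columns
#'   to adjust for (e.g. `c("age_at_index", "sex")`).
#' @param transform `"none"` (default) or `"int"` to use the
#'   inverse-normal-transformed ratio (`log_pb_int` column, computed on
#'   the fly if absent).
#' @param weak_z weak-instrument warning threshold on |slope/SE|
#'   (default 2).
#' @return object of class `abivr_stage1`: list with `beta`, `se`, `n`,
#'   `instrument`, `transform` and the underlying `lm` fit.
#' @export
fit_stage1_linear <- function(mb, exposure, instrument = "total",
                              covariates = NULL, transform = c("none", "int"),
                              weak_z = 2) {
  transform <- match.arg(transform)
  col <- instrument_column(instrument)
  dat <- merge(as.data.frame(mb), as.data.frame(exposure), by = "person_id")
  if (nrow(dat) < 3L) stop("fewer than 3 joined rows", call. = FALSE)
  if (stats::var(dat[[col]]) == 0) {
    stop("degenerate instrument: '", col, "' has zero variance",
         call. = FALSE)
  }
  y <- if (transform == "int") {
    if (is.null(dat$log_pb_int)) rank_inverse_normal(dat$log_pb) else dat$log_pb_int
  } else {
    dat$log_pb
  }
  dat$.y <- y
  rhs <- paste(c(col, covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
  sm <- summary(fit)$coefficients
  beta <- sm[col, "Estimate"]
  se <- sm[col, "Std. Error"]
  if (is.finite(se) && se > 0 && abs(beta / se) < weak_z) {
    warning("weak instrument: stage-1 |z| = ",
            format(abs(beta / se), digits = 3), " < ", weak_z, call. = FALSE)
  }
  structure(list(beta = beta, se = se, n = nrow(dat), instrument = instrument,
                 transform = transform, fit = fit),
            class = "abivr_stage1")
}

#' Stage 2: regress incident disease on the instrument
#'
#' Maximum-likelihood logistic regression of incident status on the
#' antibiotic count in the outcome cohort.  Prevalent cases are dropped
#' before fitting.  Complete or quasi-complete separation (detected via
#' non-convergence or diverging coefficients/standard errors) is an
#' error by default; with `on_separation = "flag"` a flagged result with
#' `status = "separation"` is returned instead so that a disease panel
#' can skip it with a warning.
#'
#' @param outcomes outcomes table from [define_incident_outcomes()].
#' @param exposure exposure table (sample 1), typically filtered.
#' @param disease disease name to analyse.
#' @param instrument `"total"`, `"J01CR"`, `"J01FA"` or `"J01MA"`.
#' @param covariates optional exposure-table columns to adjust for.
#' @param on_separation `"error"` (default) or `"flag"`.
#' @return object of class `abivr_stage2`: list with `beta`, `se`,
#'   `n_cases`, `n_controls`, `disease`, `instrument`, `status`
#'   (`"ok"` or `"separation"`).
#' @export
fit_stage2_logistic <- function(outcomes, exposure, disease,
                                instrument = "total", covariates = NULL,
                                on_separation = c("error", "flag")) {
  on_separation <- match.arg(on_separation)
  col <- instrument_column(instrument)
  oc <- outcomes[outcomes$disease == disease, , drop = FALSE]
  if (nrow(oc) == 0L) stop("no outcome rows for disease '", disease, "'",
                           call. = FALSE)
  oc <- oc[oc$status != "prevalent_excluded", , drop = FALSE]
  dat <- merge(oc, as.data.frame(exposure), by = "person_id")
  dat$.y <- as.integer(dat$status == "incident")
  n_cases <- sum(dat$.y == 1L)
  n_controls <- sum(dat$.y == 0L)
  if (n_cases == 0L) stop("zero incident cases for '", disease, "'",
                          call. = FALSE)
  if (n_controls == 0L) stop("zero controls for '", disease, "'",
                             call. = FALSE)
  rhs <- paste(c(col, covariates), collapse = " + ")
  fit <- suppressWarnings(
    stats::glm(stats::as.formula(paste(".y ~", rhs)), data = dat,
               family = stats::binomial(), control = stats::glm.control(
                 epsilon = 1e-8, maxit = 100))
  )
  sm <- summary(fit)$coefficients
  beta <- sm[col, "Estimate"]
  se <- sm[col, "Std. Error"]
  separated <- !fit$converged || !is.finite(beta) || !is.finite(se) ||
    abs(beta) > 15 || se > 50
  if (separated) {
    if (on_separation == "error") {
      stop("separation or non-convergence fitting '", disease, "'",
           call. = FALSE)
    }
    status <- "separation"
  } else {
    status <- "ok"
  }
  structure(list(beta = beta, se = se, n_cases = n_cases,
                 n_controls = n_controls, disease = disease,
                 instrument = instrument, status = status, fit = fit),
            class = "abivr_stage2")
}

#' Ratio-of-coefficients causal estimate with delta-method inference
#'
#' Combines a stage-1 (instrument to exposure, linear) and stage-2
#' (instrument to outcome, logistic) fit into the causal effect of the
#' exposure on the outcome:
#' \deqn{\hat\beta_{D,MB} = \hat\beta_{D,hAB} / \hat\beta_{MB,hAB}}
#' with standard error
#' \deqn{\sigma_{D,MB} = \sqrt{(\sigma_{D,hAB}^2 +
#'   \hat\beta_{D,MB}^2 \sigma_{MB,hAB}^2) / \hat\beta_{MB,hAB}^2},}
#' Wald z-score, two-sided normal p-value and confidence interval
#' `beta +/- ci_multiplier * se`.
#'
#' @param stage1 an `abivr_stage1` object (or a list with `beta`, `se`).
#' @param stage2 an `abivr_stage2` object (or a list with `beta`, `se`).
#' @param ci_multiplier half-width of the CI in standard errors
#'   (default 1.96, a 95% normal interval).
#' @param weak_z warn when stage-1 |beta/se| is below this (default 2):
#'   the delta-method variance is unreliable near a zero denominator.
#' @return object of class `abivr_estimate`: list with `beta_d_mb`,
#'   `se_d_mb`, `z`, `p`, `ci_low`, `ci_high`, `disease`, `instrument`.
#' @examples
#' s1 <- list(beta = -0.25, se = 0.05)
#' s2 <- list(beta = 0.10, se = 0.02)
#' tstsls_ratio(s1, s2)
#' @export
tstsls_ratio <- function(stage1, stage2, ci_multiplier = 1.96, weak_z = 2) {
  b_mb <- stage1$beta
  s_mb <- stage1$se
  b_d <- stage2$beta
  s_d <- stage2$se
  if (!is.finite(b_mb) || b_mb == 0) {
    stop("stage-1 coefficient is zero: ratio undefined (weak instrument)",
         call. = FALSE)
  }
  if (s_mb > 0 && abs(b_mb / s_mb) < weak_z) {
    warning("weak instrument: delta-method SE may be unreliable",
            call. = FALSE)
  }
  beta <- b_d / b_mb
  se <- sqrt((s_d^2 + beta^2 * s_mb^2) / b_mb^2)
  z <- beta / se
  structure(list(
    beta_d_mb = beta, se_d_mb = se, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    ci_low = beta - ci_multiplier * se,
    ci_high = beta + ci_multiplier * se,
    disease = if (!is.null(stage2$disease)) stage2$disease else NA_character_,
    instrument = if (!is.null(stage1$instrument)) stage1$instrument else NA_character_
  ), class = "abivr_estimate")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values with enforced monotonicity,
#' order-preserving with the input.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted p-values, same order as input.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))
  adj[order(o)]
}

#' Run the TSTSLS estimator across a disease panel
#'
#' Fits stage 1 once for the chosen instrument, then one stage-2 logistic
#' fit per disease; combines each pair with [tstsls_ratio()] and adjusts
#' p-values across the panel by Benjamini-Hochberg.  Diseases failing
#' the minimum-case threshold or exhibiting separation are reported with
#' a `status` of `"skipped_min_cases"` or `"separation"` and excluded
#' from the FDR adjustment.
#'
#' @param mb microbiome feature table (sample 2).
#' @param exposure_s2 filtered exposure table for sample 2.
#' @param exposure_s1 filtered exposure table for sample 1.
#' @param outcomes outcomes table for sample 1.
#' @param diseases character vector of disease names (must be non-empty).
#' @param instrument `"total"`, `"J01CR"`, `"J01FA"` or `"J01MA"`.
#' @param min_cases minimum incident cases per disease (default 50).
#' @param covariates optional covariate columns for both stages.
#' @param transform `"none"` or `"int"` (stage-1 exposure transform).
#' @param ci_multiplier CI half-width in SEs (default 1.96).
#' @return data frame with one row per disease: stage coefficients,
#'   causal estimate, `z`, `p`, `p_fdr`, CI bounds, case counts and
#'   `status`.  The stage-1 fit is attached as attribute `stage1`.
#' @export
run_disease_panel <- function(mb, exposure_s2, exposure_s1, outcomes,
                              diseases, instrument = "total", min_cases = 50,
                              covariates = NULL,
                              transform = c("none", "int"),
                              ci_multiplier = 1.96) {
  transform <- match.arg(transform)
  if (length(diseases) == 0L) stop("empty disease list", call. = FALSE)
  stage1 <- fit_stage1_linear(mb, exposure_s2, instrument = instrument,
                              covariates = covariates, transform = transform)

  rows <- vector("list", length(diseases))
  analysis_ids <- exposure_s1$person_id
  for (k in seq_along(diseases)) {
    d <- diseases[k]
    row <- data.frame(
      disease = d, instrument = instrument,
      n_cases = NA_integer_, n_controls = NA_integer_,
      beta_mb_hab = stage1$beta, se_mb_hab = stage1$se,
      beta_d_hab = NA_real_, se_d_hab = NA_real_,
      beta_d_mb = NA_real_, se_d_mb = NA_real_,
      z = NA_real_, p = NA_real_, p_fdr = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_,
      status = "ok", stringsAsFactors = FALSE
    )
    oc <- outcomes[outcomes$disease == d &
                     outcomes$person_id %in% analysis_ids, , drop = FALSE]
    n_inc <- sum(oc$status == "incident")
    if (n_inc < min_cases) {
      row$status <- "skipped_min_cases"
      row$n_cases <- n_inc
      rows[[k]] <- row
      next
    }
    s2 <- fit_stage2_logistic(outcomes, exposure_s1, d,
                              instrument = instrument,
                              covariates = covariates,
                              on_separation = "flag")
    row$n_cases <- s2$n_cases
    row$n_controls <- s2$n_controls
    if (s2$status != "ok") {
      warning("disease '", d, "' skipped: separation", call. = FALSE)
      row$status <- "separation"
      rows[[k]] <- row
      next
    }
    est <- tstsls_ratio(stage1, s2, ci_multiplier = ci_multiplier)
    row$beta_d_hab <- s2$beta
    row$se_d_hab <- s2$se
    row$beta_d_mb <- est$beta_d_mb
    row$se_d_mb <- est$se_d_mb
    row$z <- est$z
    row$p <- est$p
    row$ci_low <- est$ci_low
    row$ci_high <- est$ci_high
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  ok <- out$status == "ok"
  if (any(ok)) out$p_fdr[ok] <- bh_fdr(out$p[ok])
  rownames(out) <- NULL
  attr(out, "stage1") <- stage1
  out
}

#' @export
print.abivr_stage1 <- function(x, ...) {
  cat("Stage 1 (linear, exposure ~ instrument):",
      sprintf("beta = %.4f (SE %.4f), n = %d, instrument = %s%s\n",
              x$beta, x$se, x$n, x$instrument,
              if (x$transform == "int") ", INT exposure" else ""))
  invisible(x)
}

#' @export
print.abivr_stage2 <- function(x, ...) {
  cat("Stage 2 (logistic, disease ~ instrument):",
      sprintf("%s: beta = %.4f (SE %.4f), %d cases / %d controls [%s]\n",
              x$disease, x$beta, x$se, x$n_cases, x$n_controls, x$status))
  invisible(x)
}

#' @export
print.abivr_estimate <- function(x, ...) {
  cat(sprintf(
    "Causal estimate beta_D,MB = %.4f (SE %.4f), z = %.3f, p = %.3g, 95%% CI [%.4f, %.4f]\n",
    x$beta_d_mb, x$se_d_mb, x$z, x$p, x$ci_low, x$ci_high))
  invisible(x)
}
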