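mk_mb <- function(ids, y) data.frame(person_id = ids, log_pb = y,
                                     stringsAsFactors = FALSE)

mk_exposure <- function(ids, x) {
  data.frame(person_id = ids, n_ab_total = x, n_ab_J01CR = 0L,
             n_ab_J01FA = 0L, n_ab_J01MA = 0L, washout_violation = FALSE,
             age_at_index = 30L, sex = "female", eligible = TRUE,
             stringsAsFactors = FALSE)
}

mk_outcomes <- function(ids, case, disease = "d") {
  data.frame(person_id = ids, disease = disease,
             status = factor(ifelse(case, "incident", "censored_nonevent"),
                             levels = c("incident", "prevalent_excluded",
                                        "censored_nonevent")),
             first_date = NA, stringsAsFactors = FALSE)
}

test_that("stage-1 OLS matches the closed form", {
  ids <- sprintf("p%d", 1:6)
  x <- c(0, 1, 2, 3, 4, 5)
  # exact line: zero residual SE
  f0 <- suppressWarnings(fit_stage1_linear(mk_mb(ids, 2 * x),
                                           mk_exposure(ids, x)))
  expect_equal(f0$beta, 2, tolerance = 1e-10)
  expect_equal(f0$se, 0, tolerance = 1e-8)

  y <- c(1.0, 0.8, 0.9, 0.5, 0.4, 0.3)
  f <- suppressWarnings(fit_stage1_linear(mk_mb(ids, y), mk_exposure(ids, x)))
  # textbook OLS oracle
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  resid <- y - mean(y) - slope * (x - mean(x))
  se <- sqrt(sum(resid^2) / (length(x) - 2) / sxx)
  expect_equal(f$beta, slope, tolerance = 1e-12)
  expect_equal(f$se, se, tolerance = 1e-12)
  expect_equal(f$n, 6L)

  expect_error(fit_stage1_linear(mk_mb(ids, y), mk_exposure(ids, rep(2, 6))),
               "zero variance")
  expect_error(fit_stage1_linear(mk_mb(ids[1:2], y[1:2]),
                                 mk_exposure(ids[1:2], x[1:2])),
               "fewer than 3")
})

test_that("stage-1 recovers the generator's per-course effect", {
  sim <- simulate_two_samples(tiny_scenario(n_sample1 = 100, n_sample2 = 2500,
                                            seed = 31, washout_prob = 0))
  et <- build_exposure_table(sim$sample2$prescriptions, sim$sample2$subjects,
                             sim$sample2$index_dates)
  mb <- compute_log_pb(sim$sample2$genus)
  f <- fit_stage1_linear(mb, et)
  expect_lt(abs(f$beta - (-0.3)), 3 * f$se)
})

test_that("stage-2 logistic matches the binary-regressor log-odds-ratio oracle", {
  ids <- sprintf("p%03d", 1:200)
  x <- rep(c(1, 0), each = 100)
  case <- c(rep(c(TRUE, FALSE), c(10, 90)), rep(c(TRUE, FALSE), c(5, 95)))
  f <- fit_stage2_logistic(mk_outcomes(ids, case), mk_exposure(ids, x), "d")
  lor <- log((10 * 95) / (5 * 90))
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 5 + 1 / 95)
  expect_equal(f$beta, lor, tolerance = 1e-5)
  expect_equal(f$se, se, tolerance = 1e-4) # IRLS stops at deviance eps 1e-8
  expect_equal(f$n_cases, 15L)
  expect_equal(f$n_controls, 185L)

  # independence: slope near zero at large n
  set.seed(32)
  idsn <- sprintf("q%05d", 1:20000)
  xn <- rpois(20000, 2)
  cn <- runif(20000) < 0.1
  fn <- fit_stage2_logistic(mk_outcomes(idsn, cn), mk_exposure(idsn, xn), "d")
  expect_lt(abs(fn$beta), 3 * fn$se)

  # degenerate: all cases at one instrument value
  idst <- sprintf("t%d", 1:8)
  xt <- rep(c(5, 0), each = 4)
  ct <- rep(c(TRUE, FALSE), each = 4)
  expect_error(fit_stage2_logistic(mk_outcomes(idst, ct),
                                   mk_exposure(idst, xt), "d"),
               "separation")
  flagged <- fit_stage2_logistic(mk_outcomes(idst, ct),
                                 mk_exposure(idst, xt), "d",
                                 on_separation = "flag")
  expect_identical(flagged$status, "separation")
  expect_error(fit_stage2_logistic(mk_outcomes(idst, rep(FALSE, 8)),
                                   mk_exposure(idst, xt), "d"),
               "zero incident cases")
})

test_that("prevalent cases are dropped before the stage-2 fit", {
  ids <- sprintf("p%03d", 1:300)
  set.seed(33)
  x <- rpois(300, 2)
  oc <- mk_outcomes(ids, runif(300) < 0.3)
  oc$status[1:50] <- "prevalent_excluded"
  f <- fit_stage2_logistic(oc, mk_exposure(ids, x), "d")
  expect_equal(f$n_cases + f$n_controls, 250L)
})

test_that("ratio estimator reproduces the printed formulas", {
  s1 <- list(beta = -0.25, se = 0.05)
  # zero numerator
  est0 <- tstsls_ratio(s1, list(beta = 0, se = 0.02))
  expect_equal(est0$beta_d_mb, 0)
  expect_equal(est0$se_d_mb, 0.02 / 0.25)
  expect_equal(est0$z, 0)
  expect_equal(est0$p, 1)

  est <- tstsls_ratio(s1, list(beta = 0.10, se = 0.02))
  expect_equal(est$beta_d_mb, -0.4, tolerance = 1e-6)
  expect_equal(est$se_d_mb, sqrt(0.0128), tolerance = 1e-6)
  expect_equal(est$z, -0.4 / sqrt(0.0128), tolerance = 1e-6)
  expect_equal(est$p, 2 * pnorm(-abs(est$z)), tolerance = 1e-12)
  expect_equal(c(est$ci_low, est$ci_high),
               c(-0.4 - 1.96 * sqrt(0.0128), -0.4 + 1.96 * sqrt(0.0128)),
               tolerance = 1e-6)

  expect_error(tstsls_ratio(list(beta = 0, se = 0.05),
                            list(beta = 0.1, se = 0.02)), "zero")
  expect_warning(tstsls_ratio(list(beta = -0.05, se = 0.05),
                              list(beta = 0.1, se = 0.02)), "weak")
})

test_that("ratio estimator identities and equivariances hold", {
  set.seed(34)
  for (i in 1:20) {
    s1 <- list(beta = runif(1, -2, 2), se = runif(1, 0.01, 0.1))
    if (abs(s1$beta) < 0.3) s1$beta <- s1$beta + sign(s1$beta + 0.1)
    s2 <- list(beta = runif(1, -1, 1), se = runif(1, 0.01, 0.1))
    est <- suppressWarnings(tstsls_ratio(s1, s2))
    expect_equal(est$beta_d_mb * s1$beta, s2$beta, tolerance = 1e-12)
    expect_equal(sign(est$beta_d_mb), sign(s2$beta) * sign(s1$beta))
    expect_equal(est$z * est$se_d_mb, est$beta_d_mb, tolerance = 1e-12)
    expect_true(est$ci_low <= est$beta_d_mb && est$beta_d_mb <= est$ci_high)
  }

  # rescaling the microbiome exposure by c divides the estimate by c
  ids <- sprintf("p%03d", 1:500)
  set.seed(35)
  x <- rpois(500, 2)
  y <- -0.3 * x + rnorm(500)
  case <- runif(500) < plogis(-2 + 0.1 * x)
  expos <- mk_exposure(ids, x)
  oc <- mk_outcomes(ids, case)
  base_s1 <- fit_stage1_linear(mk_mb(ids, y), expos)
  base_s2 <- fit_stage2_logistic(oc, expos, "d")
  base <- tstsls_ratio(base_s1, base_s2)
  cc <- -2.5
  scaled <- tstsls_ratio(fit_stage1_linear(mk_mb(ids, cc * y), expos), base_s2)
  expect_equal(scaled$beta_d_mb, base$beta_d_mb / cc, tolerance = 1e-10)
  expect_equal(scaled$se_d_mb, base$se_d_mb / abs(cc), tolerance = 1e-10)
  expect_equal(scaled$z, sign(cc) * base$z, tolerance = 1e-10)
  expect_equal(scaled$p, base$p, tolerance = 1e-10)

  # recoding the instrument (counts doubled) leaves the estimate unchanged
  expos2 <- mk_exposure(ids, 2 * x)
  rec <- tstsls_ratio(fit_stage1_linear(mk_mb(ids, y), expos2),
                      fit_stage2_logistic(oc, expos2, "d"))
  expect_equal(rec$beta_d_mb, base$beta_d_mb, tolerance = 1e-6)
  expect_equal(rec$z, base$z, tolerance = 1e-4)
  expect_equal(rec$p, base$p, tolerance = 1e-4)
})

test_that("delta-method CI has near-nominal coverage in the strong-instrument regime", {
  set.seed(36)
  n_reps <- 500
  true_mb <- -0.25
  true_ratio <- -0.4
  b_mb <- rnorm(n_reps, true_mb, 0.03)
  b_d <- rnorm(n_reps, true_ratio * true_mb, 0.02)
  cover <- logical(n_reps)
  pnull <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    est <- tstsls_ratio(list(beta = b_mb[i], se = 0.03),
                        list(beta = b_d[i], se = 0.02))
    cover[i] <- est$ci_low <= true_ratio && true_ratio <= est$ci_high
    # and p-values under a zero effect are not anti-conservative
    est0 <- tstsls_ratio(list(beta = b_mb[i], se = 0.03),
                         list(beta = rnorm(1, 0, 0.02), se = 0.02))
    pnull[i] <- est0$p
  }
  expect_gte(mean(cover), 0.90)
  ks <- suppressWarnings(stats::ks.test(pnull, "punif",
                                        alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(37)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), stats::p.adjust(p, method = "BH"),
                 tolerance = 1e-12)
  }
})

test_that("disease panel composes one-at-a-time fits and adjusts across the panel", {
  set.seed(38)
  n <- 4000
  ids <- sprintf("p%05d", 1:n)
  x1 <- rpois(n, 2)
  ids2 <- sprintf("q%04d", 1:600)
  x2 <- rpois(600, 2)
  y2 <- -0.3 * x2 + rnorm(600, sd = 1.5)
  oc <- rbind(mk_outcomes(ids, runif(n) < plogis(-2.2 + 0.12 * x1), "dA"),
              mk_outcomes(ids, runif(n) < 0.08, "dB"),
              mk_outcomes(ids, c(runif(10) < 1, runif(n - 10) < 0.002), "dC"))
  e1 <- mk_exposure(ids, x1)
  e2 <- mk_exposure(ids2, x2)
  mb <- mk_mb(ids2, y2)
  panel <- run_disease_panel(mb, e2, e1, oc, c("dA", "dB", "dC"),
                             min_cases = 50)
  expect_equal(nrow(panel), 3L)
  expect_identical(panel$status[panel$disease == "dC"], "skipped_min_cases")
  ok <- panel[panel$status == "ok", ]
  expect_equal(ok$p_fdr, bh_fdr(ok$p), tolerance = 1e-12)

  # compositional oracle: rows equal manual stage fits + ratio
  s1 <- fit_stage1_linear(mb, e2)
  for (d in ok$disease) {
    s2 <- fit_stage2_logistic(oc, e1, d)
    man <- tstsls_ratio(s1, s2)
    row <- ok[ok$disease == d, ]
    expect_equal(row$beta_d_mb, man$beta_d_mb, tolerance = 1e-12)
    expect_equal(row$se_d_mb, man$se_d_mb, tolerance = 1e-12)
    expect_equal(row$p, man$p, tolerance = 1e-12)
  }

  # single-disease panel: FDR leaves the p-value untouched
  one <- run_disease_panel(mb, e2, e1, oc, "dA", min_cases = 50)
  expect_equal(one$p_fdr, one$p)
  expect_error(run_disease_panel(mb, e2, e1, oc, character(0)), "empty")
})
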