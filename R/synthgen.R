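# Synthetic two-sample biobank generator.
#
# Emulates the statistical structure the estimator assumes: a large
# outcome cohort (sample 1) with EHR prescription/diagnosis histories and
# a small, disjoint microbiome cohort (sample 2) with a genus table; a
# cumulative additive effect of antibiotic courses on the log P/B ratio;
# a bimodal (two-component Gaussian mixture) baseline log P/B; largely
# uncorrelated usage of the three antibiotic subclasses; binary incident
# outcomes from a logistic model on log P/B; and optional violation
# knobs (confounding, direct instrument effect, disease feedback).

AB_CLASSES <- c("J01CR", "J01FA", "J01MA", "other")

# ATC codes emitted per class; "other" spans common J01 antibiotics
# outside the three instrument subclasses.
ATC_POOL <- list(
  J01CR = c("J01CR02", "J01CR05"),
  J01FA = c("J01FA09", "J01FA10", "J01FA06"),
  J01MA = c("J01MA02", "J01MA12", "J01MA06"),
  other = c("J01CA04", "J01DB05", "J01DC02", "J01EE01", "J01XE01")
)

FILLER_GENERA <- c(
  "Faecalibacterium", "Alistipes", "Roseburia", "Blautia", "Bifidobacterium",
  "Akkermansia", "Ruminococcus", "Dorea", "Coprococcus", "Eubacterium",
  "Parabacteroides", "Oscillibacter", "Dialister", "Veillonella",
  "Streptococcus", "Lachnospira", "Butyrivibrio", "Sutterella"
)

#' Define a simulation scenario
#'
#' Returns a validated scenario object holding every knob of the
#' synthetic two-sample generator.  Defaults describe a plausible
#' mid-size European biobank: 50,000 outcome-cohort and 2,500
#' microbiome-cohort subjects; long-tailed antibiotic usage (truncated
#' negative binomial, mean 2 courses per decade, mild overdispersion);
#' per-course subclass allocation that keeps the three instrument
#' subclasses essentially uncorrelated; a bimodal baseline log P/B
#' (Bacteroides-dominant and Prevotella-dominant enterotype components);
#' and a cumulative shift of -0.3 log units per antibiotic course.
#'
#' @param n_sample1,n_sample2 cohort sizes (outcome / microbiome).
#' @param seed integer RNG seed (< 2^31 - 10).
#' @param ab_count_dist list `(mu, size, max)`: negative-binomial mean
#'   and dispersion of the 10-year total course count, truncated at
#'   `max`.
#' @param class_split probabilities allocating each course to
#'   J01CR / J01FA / J01MA / other (sums to 1).
#' @param washout_prob probability of an extra prescription inside the
#'   6-month washout window.
#' @param enterotype_mix list `(weights, means, sds)` of the
#'   two-component Gaussian mixture for baseline log P/B.
#' @param ab_effect additive change in log P/B per course: a scalar
#'   (shared across classes) or a named vector over
#'   `c("J01CR","J01FA","J01MA","other")`.
#' @param disease_specs data frame with columns `name`,
#'   `baseline_prevalence`, `causal_beta` (log-odds per unit log P/B).
#' @param confounder_strength effect of a latent standard-normal
#'   confounder on antibiotic usage (log-rate scale), log P/B and the
#'   outcome log-odds; 0 disables confounding.
#' @param direct_effect instrument-to-outcome log-odds effect per course
#'   bypassing the microbiome (exclusion-restriction violation).
#' @param feedback_strength pre-existing (latent) disease effect: adds
#'   `Pois(feedback_strength)` extra courses, shifts log P/B by
#'   `-feedback_strength`, and the disease surfaces as an early
#'   follow-up diagnosis; 0 disables the feedback loop.
#' @param age_range inclusive `(min, max)` age in years at index.
#' @param sex_ratio proportion female.
#' @param index_date_s1 fixed index date / follow-up start for sample 1.
#' @param index_window_s2 `(first, last)` dates of microbiome sampling
#'   for sample 2.
#' @param followup_end end of follow-up for outcomes.
#' @return object of class `abivr_scenario` (a validated list).
#' @export
sim_scenario <- function(n_sample1 = 50000, n_sample2 = 2500, seed = 1,
                         ab_count_dist = list(mu = 2, size = 3, max = 15),
                         class_split = c(J01CR = 0.20, J01FA = 0.25,
                                         J01MA = 0.15, other = 0.40),
                         washout_prob = 0.05,
                         enterotype_mix = list(weights = c(0.6, 0.4),
                                               means = c(-2.5, 1.0),
                                               sds = c(1.0, 1.0)),
                         ab_effect = -0.3,
                         disease_specs = data.frame(
                           name = c("disease_A", "disease_B"),
                           baseline_prevalence = c(0.05, 0.05),
                           causal_beta = c(-0.5, 0),
                           stringsAsFactors = FALSE),
                         confounder_strength = 0, direct_effect = 0,
                         feedback_strength = 0,
                         age_range = c(18, 89), sex_ratio = 0.55,
                         index_date_s1 = as.Date("2015-01-01"),
                         index_window_s2 = as.Date(c("2017-11-01",
                                                     "2020-07-31")),
                         followup_end = as.Date("2022-12-31")) {
  sc <- list(n_sample1 = n_sample1, n_sample2 = n_sample2, seed = seed,
             ab_count_dist = ab_count_dist, class_split = class_split,
             washout_prob = washout_prob, enterotype_mix = enterotype_mix,
             ab_effect = ab_effect, disease_specs = disease_specs,
             confounder_strength = confounder_strength,
             direct_effect = direct_effect,
             feedback_strength = feedback_strength,
             age_range = age_range, sex_ratio = sex_ratio,
             index_date_s1 = as.Date(index_date_s1),
             index_window_s2 = as.Date(index_window_s2),
             followup_end = as.Date(followup_end))
  validate_scenario(sc)
  class(sc) <- "abivr_scenario"
  sc
}

validate_scenario <- function(sc) {
  fail <- function(field, why) {
    stop("invalid scenario field '", field, "': ", why, call. = FALSE)
  }
  if (!is.numeric(sc$n_sample1) || sc$n_sample1 <= 0) fail("n_sample1", "must be > 0")
  if (!is.numeric(sc$n_sample2) || sc$n_sample2 <= 0) fail("n_sample2", "must be > 0")
  if (!is.numeric(sc$seed) || abs(sc$seed) >= 2^31 - 10) fail("seed", "must be a 32-bit integer")
  d <- sc$ab_count_dist
  if (!is.list(d) || is.null(d$mu) || is.null(d$size) ||
      d$mu <= 0 || d$size <= 0) fail("ab_count_dist", "needs mu > 0 and size > 0")
  cs <- sc$class_split
  if (length(cs) != 4L || any(cs < 0) || abs(sum(cs) - 1) > 1e-9) {
    fail("class_split", "four non-negative probabilities summing to 1")
  }
  if (sc$washout_prob < 0 || sc$washout_prob > 1) fail("washout_prob", "must lie in [0, 1]")
  m <- sc$enterotype_mix
  if (abs(sum(m$weights) - 1) > 1e-9 || any(m$weights < 0)) {
    fail("enterotype_mix", "weights must be non-negative and sum to 1")
  }
  if (any(m$sds <= 0)) fail("enterotype_mix", "SDs must be > 0")
  if (length(m$means) != length(m$weights) ||
      length(m$sds) != length(m$weights)) {
    fail("enterotype_mix", "weights, means, sds must have equal length")
  }
  ds <- sc$disease_specs
  if (!is.data.frame(ds) || nrow(ds) == 0L ||
      !all(c("name", "baseline_prevalence", "causal_beta") %in% names(ds))) {
    fail("disease_specs", "data frame with name, baseline_prevalence, causal_beta")
  }
  if (any(ds$baseline_prevalence <= 0 | ds$baseline_prevalence >= 1)) {
    fail("disease_specs", "baseline_prevalence must lie in (0, 1)")
  }
  if (sc$sex_ratio < 0 || sc$sex_ratio > 1) fail("sex_ratio", "must lie in [0, 1]")
  if (length(sc$age_range) != 2L || sc$age_range[1] > sc$age_range[2] ||
      sc$age_range[1] < 0) fail("age_range", "must be (min, max) with 0 <= min <= max")
  if (length(ab_effect_vector(sc)) != 4L) fail("ab_effect", "scalar or named length-4 vector")
  invisible(sc)
}

ab_effect_vector <- function(sc) {
  e <- sc$ab_effect
  if (length(e) == 1L && is.null(names(e))) {
    return(stats::setNames(rep(as.numeric(e), 4L), AB_CLASSES))
  }
  if (!all(AB_CLASSES %in% names(e))) {
    stop("invalid scenario field 'ab_effect': per-class effects need names ",
         paste(AB_CLASSES, collapse = ", "), call. = FALSE)
  }
  as.numeric(e[AB_CLASSES])
}

#' Simulate log P/B values from the generative model
#'
#' Draws baseline values from the enterotype mixture and adds the
#' cumulative antibiotic effect, an optional confounder term, and an
#' optional feedback shift:
#' `value = mixture draw + sum_class effect_class * count_class +
#' confounder_strength * confounder + feedback_shift`.
#'
#' @param n_ab_by_class integer matrix (persons x classes, columns named
#'   `J01CR`, `J01FA`, `J01MA`, `other`) of course counts; a plain
#'   vector is interpreted as total counts under a shared effect.
#' @param scenario an [sim_scenario()] object.
#' @param confounder optional numeric vector of latent confounder values
#'   (standard-normal scale), multiplied by
#'   `scenario$confounder_strength`.
#' @param feedback_shift optional additive shift (e.g. from pre-existing
#'   disease), recycled per person.
#' @return numeric vector of log P/B values.
#' @export
simulate_log_pb <- function(n_ab_by_class, scenario, confounder = NULL,
                            feedback_shift = 0) {
  eff <- ab_effect_vector(scenario)
  if (is.matrix(n_ab_by_class)) {
    if (!all(AB_CLASSES %in% colnames(n_ab_by_class))) {
      stop("count matrix needs columns ", paste(AB_CLASSES, collapse = ", "),
           call. = FALSE)
    }
    counts <- n_ab_by_class[, AB_CLASSES, drop = FALSE]
    lin <- drop(counts %*% eff)
    n <- nrow(counts)
    if (any(counts < 0)) stop("negative antibiotic counts", call. = FALSE)
  } else {
    if (any(n_ab_by_class < 0)) stop("negative antibiotic counts", call. = FALSE)
    if (length(unique(eff)) != 1L) {
      stop("per-class effects require a count matrix", call. = FALSE)
    }
    lin <- as.numeric(n_ab_by_class) * eff[1]
    n <- length(n_ab_by_class)
  }
  m <- scenario$enterotype_mix
  comp <- sample.int(length(m$weights), n, replace = TRUE, prob = m$weights)
  base <- stats::rnorm(n, mean = m$means[comp], sd = m$sds[comp])
  conf <- if (is.null(confounder)) 0 else scenario$confounder_strength * confounder
  base + lin + conf + feedback_shift
}

# Allocate each of sum(n_courses) courses to a subclass, independently
# per course.  Returns an integer matrix persons x 4.
allocate_courses <- function(n_courses, class_split) {
  n <- length(n_courses)
  total <- sum(n_courses)
  counts <- matrix(0L, n, 4L, dimnames = list(NULL, AB_CLASSES))
  if (total > 0L) {
    owner <- rep.int(seq_len(n), n_courses)
    cls <- sample.int(4L, total, replace = TRUE, prob = class_split)
    counts[] <- tabulate(owner + n * (cls - 1L), nbins = n * 4L)
  }
  counts
}

random_dates <- function(lo, hi_exclusive) {
  # one date per element, uniform on [lo, hi) at day resolution
  span <- as.integer(hi_exclusive - lo)
  lo + floor(stats::runif(length(lo)) * span)
}

simulate_cohort <- function(scenario, n, prefix, index_dates) {
  sc <- scenario
  ids <- sprintf("%s_%06d", prefix, seq_len(n))
  confounder <- stats::rnorm(n)

  # latent pre-existing disease driving the feedback loop
  ds <- sc$disease_specs
  latent_prev <- matrix(FALSE, n, nrow(ds), dimnames = list(NULL, ds$name))
  extra_ab <- integer(n)
  fb_shift <- numeric(n)
  if (sc$feedback_strength > 0) {
    for (k in seq_len(nrow(ds))) {
      latent_prev[, k] <- stats::runif(n) < ds$baseline_prevalence[k]
    }
    any_prev <- rowSums(latent_prev) > 0
    extra_ab[any_prev] <- stats::rpois(sum(any_prev), sc$feedback_strength)
    fb_shift[any_prev] <- -sc$feedback_strength
  }

  d <- sc$ab_count_dist
  mu_i <- d$mu * exp(sc$confounder_strength * confounder)
  n_total <- pmin(stats::rnbinom(n, mu = mu_i, size = d$size),
                  if (is.null(d$max)) Inf else d$max)
  n_total <- as.integer(n_total + extra_ab)
  counts <- allocate_courses(n_total, sc$class_split)

  log_pb <- simulate_log_pb(counts, sc, confounder = confounder,
                            feedback_shift = fb_shift)

  age <- floor(stats::runif(n, sc$age_range[1], sc$age_range[2] + 1))
  birth <- index_dates - age * 365L - floor(stats::runif(n) * 365)
  # completed-years age can land one year off the draw; recompute later
  sex <- ifelse(stats::runif(n) < sc$sex_ratio, "female", "male")
  subjects <- data.frame(person_id = ids,
                         birth_date = as.Date(birth, origin = "1970-01-01"),
                         sex = sex, stringsAsFactors = FALSE)

  # prescription records: counted courses in [index-10y, index-6m)
  lo <- shift_months(index_dates, -120L)
  mid <- shift_months(index_dates, -6L)
  owner <- rep.int(seq_len(n), n_total)
  cls <- rep.int(rep(1:4, n), as.vector(t(counts)))
  dates <- random_dates(lo[owner], mid[owner])
  atc <- character(length(owner))
  for (k in 1:4) {
    sel <- cls == k
    pool <- ATC_POOL[[AB_CLASSES[k]]]
    atc[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
  }
  # one prescription of one drug per day: redraw colliding dates so each
  # course remains a distinct countable record
  repeat {
    dup <- duplicated(data.frame(owner, dates, atc))
    if (!any(dup)) break
    dates[dup] <- random_dates(lo[owner[dup]], mid[owner[dup]])
  }
  rx <- data.frame(person_id = ids[owner], date = dates, atc_code = atc,
                   stringsAsFactors = FALSE)

  # washout violations: one extra prescription in [index-6m, index)
  wash <- stats::runif(n) < sc$washout_prob
  if (any(wash)) {
    wo <- which(wash)
    rx_wash <- data.frame(
      person_id = ids[wo],
      date = random_dates(mid[wo], index_dates[wo]),
      atc_code = ATC_POOL$other[
        sample.int(length(ATC_POOL$other), length(wo), replace = TRUE)],
      stringsAsFactors = FALSE)
    rx <- rbind(rx, rx_wash)
  }
  rx <- rx[order(rx$person_id, rx$date, rx$atc_code), , drop = FALSE]
  rownames(rx) <- NULL

  list(ids = ids, subjects = subjects, prescriptions = rx,
       counts = counts, n_total = n_total, log_pb = log_pb,
       confounder = confounder, latent_prev = latent_prev,
       index_dates = index_dates, washout = wash)
}

simulate_diagnoses <- function(scenario, cohort) {
  sc <- scenario
  ds <- sc$disease_specs
  n <- length(cohort$ids)
  start <- sc$index_date_s1
  end <- sc$followup_end
  gap5 <- shift_months(start, 60L)
  recs <- list()
  for (k in seq_len(nrow(ds))) {
    beta <- ds$causal_beta[k]
    alpha <- stats::qlogis(ds$baseline_prevalence[k]) -
      beta * mean(cohort$log_pb)
    eta <- alpha + beta * cohort$log_pb +
      sc$confounder_strength * cohort$confounder +
      sc$direct_effect * cohort$n_total
    case <- stats::runif(n) < stats::plogis(eta)
    prev <- cohort$latent_prev[, k]
    # pre-existing disease surfaces as a diagnosis early in follow-up
    case <- case & !prev
    dates <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
    if (any(prev)) {
      dates[prev] <- random_dates(rep(start + 1L, sum(prev)),
                                  rep(gap5, sum(prev)))
    }
    if (any(case)) {
      dates[case] <- random_dates(rep(start + 1L, sum(case)),
                                  rep(end + 1L, sum(case)))
    }
    got <- !is.na(dates)
    if (any(got)) {
      recs[[length(recs) + 1L]] <- data.frame(
        person_id = cohort$ids[got], date = dates[got],
        icd10_code = paste0(synthetic_icd_prefix(k), ".0"),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(person_id = character(0), date = as.Date(character(0)),
               icd10_code = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$person_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Synthetic diseases get ICD-10-style codes Y00.*, Y01.*, ... by panel
# position (deliberately outside real chronic-disease chapters).
synthetic_icd_prefix <- function(k) sprintf("Y%02d", k - 1L)

#' ICD-10 prefix sets for the synthetic diseases of a scenario
#'
#' @param scenario an [sim_scenario()] object.
#' @return named list of ICD-10 prefixes, one per synthetic disease,
#'   suitable for [define_incident_outcomes()].
#' @export
scenario_icd_codes <- function(scenario) {
  nm <- scenario$disease_specs$name
  stats::setNames(as.list(synthetic_icd_prefix(seq_along(nm))), nm)
}

simulate_genus_table <- function(scenario, cohort) {
  n <- length(cohort$ids)
  b <- stats::rlnorm(n, meanlog = log(20), sdlog = 0.4)
  p <- b * exp(cohort$log_pb)
  filler <- matrix(stats::rgamma(n * length(FILLER_GENERA), shape = 0.8),
                   n, length(FILLER_GENERA))
  filler_weights <- exp(-0.25 * seq_along(FILLER_GENERA))
  filler <- sweep(filler, 2L, filler_weights * 60, `*`)
  mat <- cbind(Prevotella = p, Bacteroides = b, filler)
  colnames(mat) <- c("Prevotella", "Bacteroides", FILLER_GENERA)
  mat <- mat / rowSums(mat) * 100
  mat <- round(mat, 5) # detection floor: values below 5e-6% read as zero
  data.frame(person_id = cohort$ids, mat, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Simulate paired outcome and microbiome cohorts
#'
#' Generates the two disjoint samples of the two-sample design:
#' sample 1 (outcome cohort) with subjects, prescriptions and diagnoses,
#' and sample 2 (microbiome cohort) with subjects, prescriptions and a
#' genus-level relative-abundance table.  Sample 1 uses the fixed index
#' date `scenario$index_date_s1` (start of follow-up); sample 2 subjects
#' get per-person index (sampling) dates uniform over
#' `scenario$index_window_s2`.  Output is byte-identical for a fixed
#' scenario seed.
#'
#' @param scenario an [sim_scenario()] object.
#' @return list of class `abivr_simdata` with elements `sample1`
#'   (`subjects`, `prescriptions`, `diagnoses`, `index_date`), `sample2`
#'   (`subjects`, `prescriptions`, `genus`, `index_dates`), `scenario`,
#'   and `truth` (latent log P/B, confounders and per-class counts, for
#'   diagnostics).
#' @export
simulate_two_samples <- function(scenario) {
  if (!inherits(scenario, "abivr_scenario")) {
    scenario <- do.call(sim_scenario, scenario)
  }
  validate_scenario(scenario)
  base_seed <- as.integer(scenario$seed)

  # sample 2: microbiome cohort, per-person sampling dates
  set.seed(base_seed + 1L)
  n2 <- scenario$n_sample2
  win <- scenario$index_window_s2
  idx2 <- random_dates(rep(win[1], n2), rep(win[2] + 1L, n2))
  c2 <- simulate_cohort(scenario, n2, "S2", idx2)
  genus <- simulate_genus_table(scenario, c2)

  # sample 1: outcome cohort, fixed follow-up start
  set.seed(base_seed + 2L)
  n1 <- scenario$n_sample1
  idx1 <- rep(scenario$index_date_s1, n1)
  c1 <- simulate_cohort(scenario, n1, "S1", idx1)
  diagnoses <- simulate_diagnoses(scenario, c1)

  structure(list(
    sample1 = list(subjects = c1$subjects, prescriptions = c1$prescriptions,
                   diagnoses = diagnoses,
                   index_date = scenario$index_date_s1),
    sample2 = list(subjects = c2$subjects, prescriptions = c2$prescriptions,
                   genus = genus,
                   index_dates = data.frame(person_id = c2$ids,
                                            index_date = idx2,
                                            stringsAsFactors = FALSE)),
    scenario = scenario,
    truth = list(
      log_pb_s1 = c1$log_pb, log_pb_s2 = c2$log_pb,
      counts_s1 = c1$counts, counts_s2 = c2$counts,
      confounder_s1 = c1$confounder, confounder_s2 = c2$confounder)
  ), class = "abivr_simdata")
}

#' @export
print.abivr_scenario <- function(x, ...) {
  cat("Synthetic two-sample scenario\n")
  cat(sprintf("  sample 1 (outcomes): n = %d, index %s\n",
              x$n_sample1, format(x$index_date_s1)))
  cat(sprintf("  sample 2 (microbiome): n = %d, sampling %s..%s\n",
              x$n_sample2, format(x$index_window_s2[1]),
              format(x$index_window_s2[2])))
  cat(sprintf("  AB counts: NegBin(mu = %.2g, size = %.2g), max %s\n",
              x$ab_count_dist$mu, x$ab_count_dist$size,
              format(x$ab_count_dist$max)))
  cat(sprintf("  AB effect on log P/B per course: %s\n",
              paste(format(ab_effect_vector(x)), collapse = "/")))
  cat(sprintf("  diseases: %s\n",
              paste(sprintf("%s (prev %.3g, beta %.3g)", x$disease_specs$name,
                            x$disease_specs$baseline_prevalence,
                            x$disease_specs$causal_beta), collapse = "; ")))
  cat(sprintf("  violations: confounder %.3g, direct %.3g, feedback %.3g\n",
              x$confounder_strength, x$direct_effect, x$feedback_strength))
  invisible(x)
}

#' @export
print.abivr_simdata <- function(x, ...) {
  cat("Synthetic two-sample dataset\n")
  cat(sprintf("  sample 1: %d subjects, %d prescriptions, %d diagnoses\n",
              nrow(x$sample1$subjects), nrow(x$sample1$prescriptions),
              nrow(x$sample1$diagnoses)))
  cat(sprintf("  sample 2: %d subjects, %d prescriptions, %d genera\n",
              nrow(x$sample2$subjects), nrow(x$sample2$prescriptions),
              ncol(x$sample2$genus) - 1L))
  invisible(x)
}
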