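# Instrument and outcome construction from EHR-style tables.
#
# The instrument is the number of antibiotic (ATC J01*) prescriptions in
# the window [index - years_back, index - washout_months); subjects with
# any J01* prescription inside the washout window [index - washout_months,
# index) are flagged and excluded from analysis.  Outcomes are incident
# diseases: first occurrence of a matching ICD-10 code inside the
# follow-up period, with prevalent cases excluded.

ATC_SUBCLASSES <- c("J01CR", "J01FA", "J01MA")

check_prescriptions <- function(prescriptions) {
  need <- c("person_id", "date", "atc_code")
  if (!all(need %in% names(prescriptions))) {
    stop("prescriptions must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(as.character(prescriptions$atc_code)))) {
    stop("empty atc_code in prescriptions", call. = FALSE)
  }
  prescriptions$date <- as_date_strict(prescriptions$date, "prescription date")
  prescriptions$person_id <- as.character(prescriptions$person_id)
  prescriptions$atc_code <- as.character(prescriptions$atc_code)
  # one prescription of one drug per day counts once
  prescriptions[!duplicated(prescriptions[c("person_id", "date", "atc_code")]), ,
                drop = FALSE]
}

#' Count antibiotic prescriptions in the exposure window
#'
#' Counts prescription records whose ATC code starts with `atc_prefix` and
#' whose date falls in the half-open window
#' `[index_date - years_back, index_date - washout_months)`, and flags
#' whether the person has *any* antibiotic (`J01*`) prescription in the
#' washout window `[index_date - washout_months, index_date)`.  Window
#' bounds are calendar shifts (whole months; `years_back` is rounded to
#' whole months).  Duplicate records of the same drug on the same day
#' count once; prescriptions on distinct dates each count.
#'
#' An unknown `person_id` returns a zero count with
#' `washout_violation = FALSE` rather than an error.
#'
#' @param prescriptions data frame with columns `person_id`, `date`
#'   (ISO-8601 or `Date`), `atc_code`.
#' @param person_id identifier of the subject.
#' @param index_date index date (microbiome sampling date or start of
#'   follow-up).
#' @param years_back length of the exposure window in years (default 10).
#' @param washout_months washout length in months (default 6).
#' @param atc_prefix ATC prefix selecting the instrument class
#'   (default `"J01"`, all antibiotics).
#' @return list with elements `count` (integer) and `washout_violation`
#'   (logical).
#' @examples
#' rx <- data.frame(person_id = "p1",
#'                  date = c("2010-05-03", "2004-12-31", "2014-09-15"),
#'                  atc_code = c("J01CA04", "J01FA10", "J01MA02"))
#' count_ab_in_window(rx, "p1", as.Date("2015-01-01"))
#' @export
count_ab_in_window <- function(prescriptions, person_id, index_date,
                               years_back = 10, washout_months = 6,
                               atc_prefix = "J01") {
  index_date <- as_date_strict(index_date, "index_date")
  stopifnot(length(index_date) == 1L, length(person_id) == 1L)
  if (years_back <= washout_months / 12) {
    stop("years_back must exceed washout_months/12", call. = FALSE)
  }
  rx <- check_prescriptions(prescriptions)
  rx <- rx[rx$person_id == as.character(person_id), , drop = FALSE]
  lo <- shift_months(index_date, -round(years_back * 12))
  mid <- shift_months(index_date, -round(washout_months))
  in_window <- rx$date >= lo & rx$date < mid & startsWith(rx$atc_code, atc_prefix)
  in_washout <- rx$date >= mid & rx$date < index_date &
    startsWith(rx$atc_code, "J01")
  list(count = sum(in_window), washout_violation = any(in_washout))
}

#' Build the per-person antibiotic exposure table
#'
#' One row per subject with the total `J01*` prescription count in the
#' exposure window, per-subclass counts for penicillin combinations
#' (J01CR), macrolides (J01FA) and fluoroquinolones (J01MA), the washout
#' flag, age in completed years at the index date, and an eligibility
#' flag (`eligible = !washout_violation`).
#'
#' @param prescriptions data frame with `person_id`, `date`, `atc_code`.
#' @param subjects data frame with `person_id`, `birth_date`, `sex`.
#' @param index_date either a single date used for everyone (e.g. the
#'   fixed start of follow-up) or a data frame with columns `person_id`,
#'   `index_date` giving per-person sampling dates.
#' @inheritParams count_ab_in_window
#' @return data frame of class `abivr_exposure` with columns `person_id`,
#'   `index_date`, `n_ab_total`, `n_ab_J01CR`, `n_ab_J01FA`, `n_ab_J01MA`,
#'   `washout_violation`, `age_at_index`, `sex`, `eligible`.
#' @export
build_exposure_table <- function(prescriptions, subjects, index_date,
                                 years_back = 10, washout_months = 6) {
  if (anyDuplicated(subjects$person_id)) {
    stop("duplicate person_id in subjects", call. = FALSE)
  }
  ids <- as.character(subjects$person_id)
  birth <- as_date_strict(subjects$birth_date, "birth_date")
  if (is.data.frame(index_date)) {
    m <- match(ids, as.character(index_date$person_id))
    if (anyNA(m)) stop("index_date missing for some subjects", call. = FALSE)
    idx <- as_date_strict(index_date$index_date, "index_date")[m]
  } else {
    idx <- rep(as_date_strict(index_date, "index_date"), length(ids))
  }

  rx <- check_prescriptions(prescriptions)
  p <- match(rx$person_id, ids)
  keep <- !is.na(p)
  rx <- rx[keep, , drop = FALSE]
  p <- p[keep]
  lo <- shift_months(idx, -round(years_back * 12))
  mid <- shift_months(idx, -round(washout_months))
  in_win <- rx$date >= lo[p] & rx$date < mid[p]
  in_wash <- rx$date >= mid[p] & rx$date < idx[p]
  is_ab <- startsWith(rx$atc_code, "J01")

  count_prefix <- function(prefix) {
    sel <- in_win & startsWith(rx$atc_code, prefix)
    tabulate(p[sel], nbins = length(ids))
  }
  washout <- logical(length(ids))
  washout[unique(p[in_wash & is_ab])] <- TRUE

  out <- data.frame(
    person_id = ids,
    index_date = idx,
    n_ab_total = count_prefix("J01"),
    n_ab_J01CR = count_prefix("J01CR"),
    n_ab_J01FA = count_prefix("J01FA"),
    n_ab_J01MA = count_prefix("J01MA"),
    washout_violation = washout,
    age_at_index = completed_years(birth, idx),
    sex = as.character(subjects$sex),
    stringsAsFactors = FALSE
  )
  out$eligible <- !out$washout_violation
  class(out) <- c("abivr_exposure", "data.frame")
  out
}

#' Restrict the exposure table to the analysis set
#'
#' Keeps washout-eligible subjects inside the age range (inclusive) whose
#' instrument count does not exceed `max_ab`.  The default settings
#' (ages 23-50, at most 5 antibiotic courses) target the healthier part
#' of the population; sensitivity settings widen them (ages 23-89,
#' cap 10).  When a subclass instrument is selected the cap applies to
#' that subclass count, while washout eligibility always refers to all
#' `J01*` antibiotics.
#'
#' @param exposure an exposure table from [build_exposure_table()].
#' @param min_age,max_age inclusive age bounds in completed years.
#' @param max_ab inclusive cap on the instrument count.
#' @param instrument which count the cap applies to: `"total"` or one of
#'   `"J01CR"`, `"J01FA"`, `"J01MA"`.
#' @param sex optional filter: `"all"` (default), `"female"` or `"male"`.
#' @return the filtered exposure table (possibly zero rows, with a
#'   warning).
#' @export
filter_analysis_set <- function(exposure, min_age = 23, max_age = 50,
                                max_ab = 5, instrument = "total",
                                sex = c("all", "female", "male")) {
  stopifnot(min_age <= max_age, max_ab >= 0)
  sex <- match.arg(sex)
  col <- instrument_column(instrument)
  keep <- exposure$eligible &
    exposure$age_at_index >= min_age & exposure$age_at_index <= max_age &
    exposure[[col]] <= max_ab
  if (sex != "all") keep <- keep & exposure$sex == sex
  out <- exposure[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("analysis set is empty", call. = FALSE)
  out
}

instrument_column <- function(instrument) {
  instrument <- match.arg(instrument, c("total", ATC_SUBCLASSES))
  if (instrument == "total") "n_ab_total" else paste0("n_ab_", instrument)
}

#' Define incident disease outcomes
#'
#' For each subject and disease, classifies the first matching ICD-10
#' diagnosis: `incident` if it falls in
#' `(followup_start + gap_years, followup_end]`, `prevalent_excluded` if
#' it falls on or before `followup_start + gap_years` (with
#' `gap_years = 5` this implements the sensitivity rule treating the
#' first five follow-up years as prevalent), and `censored_nonevent`
#' otherwise.  Diagnoses after `followup_end` are ignored (observations
#' are right-censored at the end of follow-up).  ICD-10 codes are
#' matched by prefix, so `"K58"` matches `"K58.0"`.
#'
#' @param diagnoses data frame with columns `person_id`, `date`,
#'   `icd10_code`.
#' @param subjects data frame with a `person_id` column.
#' @param icd_codes named list: one character vector of ICD-10 prefixes
#'   per disease.
#' @param followup_start,followup_end follow-up window (defaults
#'   2015-01-01 and 2022-12-31).
#' @param gap_years years of incidence after `followup_start` to treat
#'   as prevalent (default 0; rounded to whole months).
#' @return data frame of class `abivr_outcomes` with columns
#'   `person_id`, `disease`, `status` (factor with the three levels) and
#'   `first_date` (`Date`, `NA` when there is no matching diagnosis).
#' @export
define_incident_outcomes <- function(diagnoses, subjects, icd_codes,
                                     followup_start = as.Date("2015-01-01"),
                                     followup_end = as.Date("2022-12-31"),
                                     gap_years = 0) {
  if (!is.list(icd_codes) || length(icd_codes) == 0L ||
      is.null(names(icd_codes)) || any(!nzchar(names(icd_codes)))) {
    stop("icd_codes must be a non-empty named list of ICD-10 prefixes",
         call. = FALSE)
  }
  followup_start <- as_date_strict(followup_start, "followup_start")
  followup_end <- as_date_strict(followup_end, "followup_end")
  stopifnot(followup_start < followup_end)
  gap_end <- shift_months(followup_start, round(gap_years * 12))

  dx <- diagnoses
  dx$date <- as_date_strict(dx$date, "diagnosis date")
  dx$person_id <- as.character(dx$person_id)
  dx$icd10_code <- as.character(dx$icd10_code)
  if (any(!nzchar(dx$icd10_code))) stop("empty icd10_code", call. = FALSE)
  ids <- as.character(subjects$person_id)

  res <- vector("list", length(icd_codes))
  for (k in seq_along(icd_codes)) {
    prefixes <- icd_codes[[k]]
    hit <- Reduce(`|`, lapply(prefixes, function(p) startsWith(dx$icd10_code, p)))
    sub <- dx[hit & dx$person_id %in% ids & dx$date <= followup_end, , drop = FALSE]
    first <- as.Date(rep(NA, length(ids)))
    if (nrow(sub)) {
      agg <- tapply(as.numeric(sub$date), sub$person_id, min)
      m <- match(names(agg), ids)
      first[m] <- as.Date(as.numeric(agg), origin = "1970-01-01")
    }
    status <- rep("censored_nonevent", length(ids))
    status[!is.na(first) & first <= gap_end] <- "prevalent_excluded"
    status[!is.na(first) & first > gap_end] <- "incident"
    res[[k]] <- data.frame(
      person_id = ids,
      disease = names(icd_codes)[k],
      status = status,
      first_date = first,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  out$status <- factor(out$status,
                       levels = c("incident", "prevalent_excluded",
                                  "censored_nonevent"))
  rownames(out) <- NULL
  class(out) <- c("abivr_outcomes", "data.frame")
  out
}

#' Keep diseases with enough incident cases
#'
#' @param outcomes an outcomes table from [define_incident_outcomes()].
#' @param min_cases minimum number of incident cases (default 50).
#' @param persons optional vector of person ids restricting the tally to
#'   the current analysis set.
#' @return character vector of disease names meeting the threshold.
#' @export
case_count_filter <- function(outcomes, min_cases = 50, persons = NULL) {
  oc <- outcomes
  if (!is.null(persons)) oc <- oc[oc$person_id %in% persons, , drop = FALSE]
  tallies <- tapply(oc$status == "incident", oc$disease, sum)
  names(tallies)[!is.na(tallies) & tallies >= min_cases]
}
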