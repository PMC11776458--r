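test_that("window counting matches the worked prescription history", {
  rx <- data.frame(person_id = "p1",
                   date = c("2010-05-03", "2004-12-31", "2014-09-15"),
                   atc_code = c("J01CA04", "J01FA10", "J01MA02"))
  res <- count_ab_in_window(rx, "p1", as.Date("2015-01-01"))
  expect_equal(res$count, 1L)      # 2010 record; 2004 is outside the window
  expect_true(res$washout_violation) # 2014-09-15 is within 6 months

  # person with no records: zero count, no violation, no error
  res0 <- count_ab_in_window(rx, "nobody", as.Date("2015-01-01"))
  expect_equal(res0$count, 0L)
  expect_false(res0$washout_violation)

  expect_error(count_ab_in_window(
    data.frame(person_id = "p1", date = "not-a-date", atc_code = "J01CA04"),
    "p1", as.Date("2015-01-01")), "malformed")
  expect_error(count_ab_in_window(rx, "p1", as.Date("2015-01-01"),
                                  years_back = 0.4), "years_back")
})

test_that("boundary dates follow the half-open window convention", {
  idx <- as.Date("2015-01-01")
  rx <- data.frame(
    person_id = "p",
    date = c("2005-01-01",  # exactly index - 10y: counted (closed low end)
             "2004-12-31",  # one day earlier: out
             "2014-06-30",  # last countable day before washout
             "2014-07-01",  # exactly index - 6m: washout, not counted
             "2014-12-31"), # day before index: washout
    atc_code = "J01AA01")
  res <- count_ab_in_window(rx, "p", idx)
  expect_equal(res$count, 2L)
  expect_true(res$washout_violation)
  # same-day duplicates of the same drug count once
  dup <- rbind(rx, rx[1, ])
  expect_equal(count_ab_in_window(dup, "p", idx)$count, 2L)
})

test_that("exposure table counts subclasses by prefix and flags washout", {
  idx <- as.Date("2015-01-01")
  subjects <- data.frame(person_id = c("a", "b", "c"),
                         birth_date = c("1980-06-15", "1990-01-01",
                                        "1964-01-02"),
                         sex = c("female", "male", "female"))
  rx <- data.frame(
    person_id = c("a", "a", "a", "a", "b"),
    date = c("2010-01-10", "2011-02-11", "2012-03-12", "2013-04-13",
             "2014-11-01"),
    atc_code = c("J01CR02", "J01CR05", "J01FA09", "J01CC01", "J01MA02"))
  et <- build_exposure_table(rx, subjects, idx)
  a <- et[et$person_id == "a", ]
  expect_equal(a$n_ab_total, 4L)
  expect_equal(a$n_ab_J01CR, 2L)
  expect_equal(a$n_ab_J01FA, 1L)
  expect_equal(a$n_ab_J01MA, 0L)
  expect_true(a$eligible)
  b <- et[et$person_id == "b", ]
  expect_true(b$washout_violation)
  expect_false(b$eligible)
  # ages in completed years at index
  expect_equal(et$age_at_index, c(34L, 25L, 50L))
  # empty prescriptions: all zero, all eligible
  e0 <- build_exposure_table(rx[0, ], subjects, idx)
  expect_true(all(e0$n_ab_total == 0L) && all(e0$eligible))
  expect_error(build_exposure_table(rx, rbind(subjects, subjects[1, ]), idx),
               "duplicate")
})

test_that("analysis-set filter applies inclusive bounds and widens monotonically", {
  et <- build_exposure_table(
    data.frame(person_id = character(0), date = character(0),
               atc_code = character(0)),
    data.frame(person_id = c("x", "y", "z"),
               birth_date = c("1963-12-31", "1965-01-01", "1991-12-31"),
               sex = "female"),
    as.Date("2015-01-01"))
  et$n_ab_total <- c(3L, 5L, 6L)
  # x: age 51 by 2015-01-01 -> excluded; y: age 50, 5 AB -> retained
  f <- filter_analysis_set(et)
  expect_identical(f$person_id, "y")
  wide <- filter_analysis_set(et, max_age = 89, max_ab = 10)
  expect_true(all(f$person_id %in% wide$person_id))
  expect_true(all(c("x", "z") %in% wide$person_id))
  expect_warning(filter_analysis_set(et, min_age = 23, max_age = 23),
                 "empty")
})

test_that("incident/prevalent/censored classification honours the gap rule", {
  subjects <- data.frame(person_id = c("p1", "p2", "p3", "p4"),
                         birth_date = "1980-01-01", sex = "female")
  dx <- data.frame(
    person_id = c("p1", "p2", "p4"),
    date = c("2013-06-01", "2016-03-10", "2023-05-01"),
    icd10_code = c("K58.0", "K58.9", "K58.1"))
  codes <- list(ibs = "K58")
  oc <- define_incident_outcomes(dx, subjects, codes)
  get <- function(o, p) as.character(o$status[o$person_id == p])
  expect_equal(get(oc, "p1"), "prevalent_excluded")  # diagnosed pre-2015
  expect_equal(get(oc, "p2"), "incident")
  expect_equal(get(oc, "p3"), "censored_nonevent")   # never diagnosed
  expect_equal(get(oc, "p4"), "censored_nonevent")   # after end of follow-up
  # with a 5-year gap the 2016 diagnosis becomes prevalent
  oc5 <- define_incident_outcomes(dx, subjects, codes, gap_years = 5)
  expect_equal(get(oc5, "p2"), "prevalent_excluded")
  # statuses partition every person x disease exactly once
  expect_equal(nrow(oc), length(subjects$person_id) * length(codes))
  expect_false(anyNA(oc$status))
  expect_error(define_incident_outcomes(dx, subjects, list()), "icd_codes")
})

test_that("case-count filter keeps diseases at the threshold", {
  ids <- sprintf("p%03d", 1:200)
  oc <- rbind(
    data.frame(person_id = ids, disease = "common",
               status = ifelse(seq_along(ids) <= 50, "incident",
                               "censored_nonevent"),
               first_date = NA),
    data.frame(person_id = ids, disease = "rare",
               status = ifelse(seq_along(ids) <= 49, "incident",
                               "censored_nonevent"),
               first_date = NA))
  oc$status <- factor(oc$status, levels = c("incident", "prevalent_excluded",
                                            "censored_nonevent"))
  expect_identical(case_count_filter(oc, 50), "common")
  # restriction to an analysis subset changes the tally
  expect_identical(case_count_filter(oc, 50, persons = ids[1:40]),
                   character(0))
})

test_that("washout shortening can only increase the count", {
  set.seed(101)
  idx <- as.Date("2016-06-15")
  for (i in 1:25) {
    rx <- random_prescriptions(30, "p", idx - 4200, idx - 1)
    with_wash <- count_ab_in_window(rx, "p", idx, washout_months = 6)$count
    no_wash <- count_ab_in_window(rx, "p", idx, washout_months = 0)$count
    expect_lte(with_wash, no_wash)
  }
})
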