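# Calendar helpers shared by the cohort-construction functions.
#
# Exposure windows are defined in calendar months/years, so all window
# arithmetic is done on the calendar (POSIXlt), never with 365.25-day
# approximations.  Day-of-month is clamped to the target month's length
# (e.g. 2015-03-31 minus 1 month -> 2015-02-28).

#' Shift dates by whole calendar months
#'
#' @param dates a `Date` vector.
#' @param months integer number of months to add (negative to go back).
#' @return a `Date` vector of the same length.
#' @keywords internal
#' @noRd
shift_months <- function(dates, months) {
  lt <- as.POSIXlt(dates)
  day <- lt$mday
  lt$mday <- 1L
  lt$mon <- lt$mon + as.integer(months)
  lt <- as.POSIXlt(as.Date(lt)) # renormalise year/month
  last <- days_in_month(lt$year + 1900L, lt$mon + 1L)
  lt$mday <- pmin(day, last)
  as.Date(lt)
}

days_in_month <- function(year, month) {
  n <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  ifelse(month == 2L & leap, 29L, n)
}

#' Parse a date column strictly
#'
#' @param x a vector coercible to `Date` (ISO-8601 strings or `Date`).
#' @param what label used in the error message.
#' @return a `Date` vector; malformed entries raise an error.
#' @keywords internal
#' @noRd
as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) {
    if (anyNA(x)) stop("missing values in ", what, call. = FALSE)
    return(x)
  }
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- is.na(out) & !is.na(x)
  if (any(bad) || anyNA(x)) {
    stop("malformed ", what, ": ",
         paste(utils::head(unique(as.character(x)[bad | is.na(x)]), 3L),
               collapse = ", "),
         call. = FALSE)
  }
  out
}

# Age in completed years at `at` for subjects born on `birth`.
completed_years <- function(birth, at) {
  bl <- as.POSIXlt(birth)
  al <- as.POSIXlt(at)
  age <- al$year - bl$year
  before_birthday <- al$mon < bl$mon | (al$mon == bl$mon & al$mday < bl$mday)
  age - as.integer(before_birthday)
}
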