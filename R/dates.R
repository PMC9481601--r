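# Partial calendar dates.
#
# Spontaneous reports record dates at year, year/month or year/month/day
# precision, and often not at all. A partial date is carried as a canonical
# string: "YYYY", "YYYY-MM", "YYYY-MM-DD", or "" when missing. Missing dates
# are never encoded as sentinel years.

#' Parse partial dates
#'
#' Accepts ISO-like strings with `-`, `/` or `.` separators as well as the
#' compact `YYYYMMDD` / `YYYYMM` forms. Anything unparseable (including
#' out-of-range months or days) yields a missing date rather than an error,
#' so malformed records never drop rows.
#'
#' @param x character vector of date strings.
#' @return data.frame with integer columns `year`, `month`, `day` (NA where
#'   absent). A fully missing date has all three NA.
#' @export
parse_partial_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  n <- length(x)
  year <- month <- day <- rep(NA_integer_, n)

  sep <- gsub("[/.]", "-", x)
  m3 <- regmatches(sep, regexec("^([0-9]{4})-([0-9]{1,2})-([0-9]{1,2})$", sep))
  m2 <- regmatches(sep, regexec("^([0-9]{4})-([0-9]{1,2})$", sep))
  m1 <- regmatches(sep, regexec("^([0-9]{4})$", sep))
  c8 <- regmatches(x, regexec("^([0-9]{4})([0-9]{2})([0-9]{2})$", x))
  c6 <- regmatches(x, regexec("^([0-9]{4})([0-9]{2})$", x))

  pick <- function(mm, i) as.integer(vapply(mm, function(m) {
    if (length(m)) m[i + 1L] else NA_character_
  }, character(1)))

  for (mm in list(m3, c8)) {
    y <- pick(mm, 1); mo <- pick(mm, 2); d <- pick(mm, 3)
    ok <- !is.na(y) & is.na(year)
    year[ok] <- y[ok]; month[ok] <- mo[ok]; day[ok] <- d[ok]
  }
  for (mm in list(m2, c6)) {
    y <- pick(mm, 1); mo <- pick(mm, 2)
    ok <- !is.na(y) & is.na(year)
    year[ok] <- y[ok]; month[ok] <- mo[ok]
  }
  y <- pick(m1, 1)
  ok <- !is.na(y) & is.na(year)
  year[ok] <- y[ok]

  bad_m <- !is.na(month) & (month < 1L | month > 12L)
  bad_d <- !is.na(day) & (day < 1L | day > 31L)
  bad <- bad_m | bad_d
  year[bad] <- month[bad] <- day[bad] <- NA_integer_
  # day present implies month present by construction of the patterns
  data.frame(year = year, month = month, day = day)
}

#' Serialize partial dates to the canonical string form
#'
#' @param pd data.frame as returned by [parse_partial_date()].
#' @return character vector: `"YYYY-MM-DD"`, `"YYYY-MM"`, `"YYYY"` or `""`.
#' @export
format_partial_date <- function(pd) {
  out <- character(nrow(pd))
  has_y <- !is.na(pd$year)
  has_m <- has_y & !is.na(pd$month)
  has_d <- has_m & !is.na(pd$day)
  out[has_y] <- sprintf("%04d", pd$year[has_y])
  out[has_m] <- sprintf("%04d-%02d", pd$year[has_m], pd$month[has_m])
  out[has_d] <- sprintf("%04d-%02d-%02d", pd$year[has_d], pd$month[has_d],
                        pd$day[has_d])
  out
}

#' Canonicalize date strings
#'
#' Parse-then-format: any accepted dialect comes out in the canonical
#' `YYYY[-MM[-DD]]` form; unparseable input comes out as `""`.
#'
#' @param x character vector of date strings.
#' @return character vector of canonical partial dates.
#' @export
canonicalize_date <- function(x) {
  format_partial_date(parse_partial_date(x))
}

#' Resolve partial dates to calendar dates
#'
#' Year/month records are resolved to a configurable day of the month
#' (default the 1st, a conservative choice for onset-interval arithmetic).
#' Year-only and fully missing records resolve to `NA`: a bare year is too
#' coarse for day-scale intervals.
#'
#' @param x character vector of partial-date strings.
#' @param month_day day of month used to resolve year/month records.
#' @return a `Date` vector with `NA` where resolution is impossible.
#' @export
resolve_date <- function(x, month_day = 1L) {
  pd <- parse_partial_date(x)
  day <- ifelse(is.na(pd$day), month_day, pd$day)
  out <- rep(as.Date(NA), nrow(pd))
  ok <- !is.na(pd$year) & !is.na(pd$month)
  if (any(ok)) {
    out[ok] <- as.Date(sprintf("%04d-%02d-%02d", pd$year[ok], pd$month[ok],
                               day[ok]))
  }
  out
}
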