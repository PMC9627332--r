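#' Parse a FAERS-style partial date
#'
#' FAERS date fields carry 4 (`YYYY`), 6 (`YYYYMM`) or 8 (`YYYYMMDD`) digit
#' strings; many reports only know the year or month of an event. Partial
#' dates are kept partial -- nothing is imputed at parse time -- and each
#' downstream stage decides whether a given precision is usable.
#'
#' @param x Character vector of date strings. Empty strings and `NA` denote
#'   an absent date.
#' @return A tibble with one row per input and integer columns `year`,
#'   `month`, `day` (`NA` for absent components), plus a logical `valid`
#'   column. Rows that are non-empty but malformed (wrong length,
#'   non-numeric, month outside 1..12, day invalid for the month) have
#'   `valid = FALSE` and all components `NA`.
#' @examples
#' parse_partial_date(c("2016", "201603", "20160229", "20160231", ""))
#' @export
parse_partial_date <- function(x) {
  x <- as.character(x)
  n <- length(x)
  year <- month <- day <- rep(NA_integer_, n)
  valid <- rep(TRUE, n)

  blank <- is.na(x) | trimws(x) == ""
  x[!blank] <- trimws(x[!blank])
  todo <- !blank

  ok_form <- todo & grepl("^[0-9]+$", x) & nchar(x) %in% c(4L, 6L, 8L)
  valid[todo & !ok_form] <- FALSE

  year[ok_form] <- as.integer(substr(x[ok_form], 1L, 4L))
  has_m <- ok_form & nchar(x) >= 6L
  month[has_m] <- as.integer(substr(x[has_m], 5L, 6L))
  has_d <- ok_form & nchar(x) == 8L
  day[has_d] <- as.integer(substr(x[has_d], 7L, 8L))

  bad_m <- has_m & (month < 1L | month > 12L)
  # calendar validity of the day, leap years included
  bad_d <- has_d & !bad_m
  if (any(bad_d)) {
    iso <- sprintf("%04d-%02d-%02d", year[bad_d], month[bad_d], day[bad_d])
    bad_d[bad_d] <- is.na(as.Date(iso, format = "%Y-%m-%d"))
  }
  bad <- bad_m | bad_d
  valid[bad] <- FALSE
  year[bad] <- month[bad] <- day[bad] <- NA_integer_
  month[bad_m] <- NA_integer_

  tibble::tibble(year = year, month = month, day = day, valid = valid)
}

#' Test whether a partial-date string has full day precision
#'
#' @param x Character vector of partial-date strings.
#' @return Logical vector: `TRUE` where the string is a valid `YYYYMMDD`
#'   calendar date.
#' @export
has_day_precision <- function(x) {
  p <- parse_partial_date(x)
  p$valid & !is.na(p$day)
}

#' Convert fully-specified partial-date strings to `Date`
#'
#' @param x Character vector of partial-date strings.
#' @return A `Date` vector; `NA` wherever the input lacks day precision or
#'   is invalid.
#' @export
partial_date_to_date <- function(x) {
  p <- parse_partial_date(x)
  out <- rep(as.Date(NA), length(x))
  full <- p$valid & !is.na(p$day)
  out[full] <- as.Date(sprintf("%04d-%02d-%02d",
                               p$year[full], p$month[full], p$day[full]))
  out
}

# round half away from zero, the convention used for printed percentages
round_half_up <- function(x, digits = 2L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
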