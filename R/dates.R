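# FAERS date fields are integer-like strings: YYYYMMDD (full precision),
# YYYYMM or YYYY (partial), or blank. Partial dates are retained as-is so the
# time-to-onset stage can exclude them explicitly rather than silently padding.

#' Normalize a FAERS date string
#'
#' Trims whitespace and validates that the value is a 4, 6 or 8 digit string.
#' Anything else (including blanks and `NA`) becomes `NA_character_`.
#'
#' @param x Character vector of raw date fields.
#' @return Character vector with invalid entries set to `NA`.
#' @keywords internal
normalize_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[!grepl("^(\\d{4}|\\d{6}|\\d{8})$", x)] <- NA_character_
  x
}

#' Precision of a FAERS date
#'
#' @param x Character vector of normalized FAERS dates.
#' @return `"day"`, `"month"`, `"year"` or `NA` per element.
#' @export
faers_date_precision <- function(x) {
  out <- rep(NA_character_, length(x))
  nc <- nchar(x)
  out[!is.na(x) & nc == 8L] <- "day"
  out[!is.na(x) & nc == 6L] <- "month"
  out[!is.na(x) & nc == 4L] <- "year"
  out
}

#' Convert full-precision FAERS dates to days since epoch
#'
#' Partial (year/month) and missing dates map to `NA`; so do calendar-invalid
#' 8-digit values such as `20220230`.
#'
#' @param x Character vector of normalized FAERS dates.
#' @return Integer vector of days since 1970-01-01.
#' @export
faers_date_days <- function(x) {
  out <- rep(NA_integer_, length(x))
  full <- !is.na(x) & nchar(x) == 8L
  if (any(full)) {
    d <- as.Date(x[full], format = "%Y%m%d")
    out[full] <- as.integer(d)
  }
  out
}

#' Numeric sort key for FAERS dates (partial dates allowed)
#'
#' Right-pads partial dates with zeros so that `20220301 > 202202 > 2021`.
#' Used only for ordering (deduplication); never for arithmetic.
#'
#' @param x Character vector of normalized FAERS dates.
#' @return Numeric vector; `NA` dates sort lowest.
#' @keywords internal
faers_date_key <- function(x) {
  key <- suppressWarnings(as.numeric(x) * 10^(8L - nchar(x)))
  key[is.na(key)] <- -Inf
  key
}

#' Year component of a FAERS date
#' @param x Character vector of normalized FAERS dates.
#' @return Integer year or `NA`.
#' @keywords internal
faers_date_year <- function(x) {
  suppressWarnings(as.integer(substr(x, 1L, 4L)))
}

#' Format days-since-epoch back to YYYYMMDD
#' @param days Integer days since 1970-01-01.
#' @return Character vector of 8-digit dates.
#' @keywords internal
days_to_faers_date <- function(days) {
  out <- rep(NA_character_, length(days))
  ok <- !is.na(days)
  out[ok] <- format(as.Date(days[ok], origin = "1970-01-01"), "%Y%m%d")
  out
}
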