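# FAERS dates are plain digit strings: YYYYMMDD, YYYYMM or YYYY. Partial
# dates are common and must be carried with an explicit precision tag so that
# downstream date arithmetic (deduplication order, time-to-onset, therapy
# duration) can require day precision rather than silently imputing.

#' Parse FAERS date strings with a precision tag
#'
#' A total function: every input yields a row. Eight digits parse to day
#' precision, six to month, four to year; anything else (including
#' calendar-impossible values such as month 13) yields precision `"none"`
#' and an `NA` date. Partial dates are anchored at the first day of the
#' month/year purely so a `Date` can be carried; the precision tag governs
#' whether arithmetic is allowed.
#'
#' @param x character (or numeric) vector of raw date fields.
#' @return data.frame with columns `date` (`Date`) and `precision`
#'   (character, one of `"day"`, `"month"`, `"year"`, `"none"`).
#' @examples
#' faers_parse_date(c("20200131", "202001", "2020", "20201332", ""))
#' @export
faers_parse_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  n <- length(x)
  date <- rep(as.Date(NA), n)
  precision <- rep("none", n)

  digits <- grepl("^[0-9]+$", x)

  i8 <- digits & nchar(x) == 8L
  if (any(i8)) {
    d <- as.Date(x[i8], format = "%Y%m%d")
    ok <- !is.na(d)
    date[i8][ok] <- d[ok]
    precision[i8][ok] <- "day"
  }
  i6 <- digits & nchar(x) == 6L
  if (any(i6)) {
    mon <- as.integer(substr(x[i6], 5L, 6L))
    ok <- !is.na(mon) & mon >= 1L & mon <= 12L
    d <- as.Date(paste0(x[i6][ok], "01"), format = "%Y%m%d")
    date[i6][ok] <- d
    precision[i6][ok] <- "month"
  }
  i4 <- digits & nchar(x) == 4L
  if (any(i4)) {
    yr <- as.integer(x[i4])
    ok <- yr >= 1000L & yr <= 9999L
    date[i4][ok] <- as.Date(paste0(x[i4][ok], "0101"), format = "%Y%m%d")
    precision[i4][ok] <- "year"
  }

  data.frame(date = date, precision = precision, stringsAsFactors = FALSE)
}

# internal: calendar quarter label ("2023Q1") for a Date vector
quarter_label <- function(d) {
  paste0(format(d, "%Y"), "Q", (as.integer(format(d, "%m")) - 1L) %/% 3L + 1L)
}
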