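# FAERS dates are bare digit strings: YYYYMMDD (day precision), YYYYMM
# (month precision) or YYYY (year precision).  Partial dates are retained
# with an explicit precision flag; only day-precision dates ever become
# Date objects, so day-level arithmetic (time to onset) can never operate
# on an imputed day.

#' Parse FAERS-style digit-string dates
#'
#' @param x Character vector of `YYYYMMDD`, `YYYYMM` or `YYYY` strings
#'   (empty or malformed values yield precision `"missing"`).
#' @return A data.frame with columns `raw` (input), `precision` (one of
#'   `"day"`, `"month"`, `"year"`, `"missing"`), `date` (a `Date`, `NA`
#'   unless day precision) and `year` (integer, `NA` if missing).
#' @keywords internal
parseFaersDate <- function(x) {
  x <- ifelse(is.na(x), "", trimws(as.character(x)))
  n <- nchar(x)
  digits <- grepl("^[0-9]+$", x)
  precision <- rep("missing", length(x))
  precision[digits & n == 8L] <- "day"
  precision[digits & n == 6L] <- "month"
  precision[digits & n == 4L] <- "year"
  date <- rep(as.Date(NA), length(x))
  day <- precision == "day"
  if (any(day)) {
    parsed <- as.Date(x[day], format = "%Y%m%d")
    date[day] <- parsed
    # 20190231-style impossible dates demote to month precision
    bad <- is.na(parsed)
    if (any(bad)) precision[which(day)[bad]] <- "month"
  }
  year <- rep(NA_integer_, length(x))
  hasYear <- precision != "missing"
  year[hasYear] <- as.integer(substr(x[hasYear], 1L, 4L))
  data.frame(raw = x, precision = precision, date = date, year = year,
             stringsAsFactors = FALSE)
}

#' Format a Date as a FAERS digit string
#' @keywords internal
formatFaersDate <- function(d) {
  out <- rep("", length(d))
  ok <- !is.na(d)
  out[ok] <- format(d[ok], "%Y%m%d")
  out
}

# Ordering rank for primaryid tie-breaks: digit strings of equal length
# compare lexicographically, otherwise the longer (numerically larger)
# string wins.  Implemented by left-padding to a common width.
primaryidRank <- function(primaryid) {
  primaryid <- as.character(primaryid)
  width <- max(nchar(primaryid), 1L)
  formatC(primaryid, width = width, flag = "0")
}
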