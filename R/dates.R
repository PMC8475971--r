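# Partial calendar dates.
#
# Registry and bibliographic records carry dates at day, month, or year
# precision ("2020-03-15", "2020-03", "March 2020", "2020"). Month precision
# is imputed to the first day of the month and year precision to January 1,
# and the original precision travels alongside the imputed value so interval
# arithmetic can be footnoted (or refused) downstream. No date arithmetic in
# the package ever consumes a missing date: every consumer guards on NA.

.month_names <- c(
  january = 1, february = 2, march = 3, april = 4, may = 5, june = 6,
  july = 7, august = 8, september = 9, october = 10, november = 11,
  december = 12,
  jan = 1, feb = 2, mar = 3, apr = 4, jun = 6, jul = 7, aug = 8,
  sep = 9, oct = 10, nov = 11, dec = 12
)

#' Resolve a possibly partial date string
#'
#' Accepts `YYYY-MM-DD`, `YYYY-MM`, `YYYY`, `"Month YYYY"` (full or
#' three-letter English month names, as in registry exports and PubMed
#' `MedlineDate` fields), and `"Month D, YYYY"`. Month-precision dates
#' resolve to the first day of the month and year-precision dates to
#' January 1; the precision flag is retained for downstream interval
#' arithmetic. `NA` or empty input yields a missing date with precision
#' `"missing"`.
#'
#' @param x character vector of date strings.
#' @return data.frame with columns `date` ([Date]) and `precision`
#'   (one of `"day"`, `"month"`, `"year"`, `"missing"`).
#' @export
#' @examples
#' resolve_partial_date(c("June 2021", "2021-08-15", "2023"))
resolve_partial_date <- function(x) {
  x <- as.character(x)
  n <- length(x)
  date <- rep(as.Date(NA), n)
  precision <- rep("missing", n)
  for (i in seq_len(n)) {
    s <- trimws(x[[i]])
    if (is.na(s) || s == "") next
    if (grepl("^\\d{4}-\\d{2}-\\d{2}$", s)) {
      d <- as.Date(s, format = "%Y-%m-%d")
      if (is.na(d)) abort(sprintf("unparseable calendar date: '%s'", s), "trialpubs_parse_error")
      date[i] <- d; precision[i] <- "day"
    } else if (grepl("^\\d{4}-\\d{2}$", s)) {
      date[i] <- as.Date(paste0(s, "-01")); precision[i] <- "month"
    } else if (grepl("^\\d{4}$", s)) {
      date[i] <- as.Date(paste0(s, "-01-01")); precision[i] <- "year"
    } else if (grepl("^[A-Za-z]+ \\d{1,2}, \\d{4}$", s)) {
      parts <- strsplit(s, "[ ,]+")[[1]]
      m <- .month_names[tolower(parts[1])]
      if (is.na(m)) abort(sprintf("unrecognized month in date: '%s'", s), "trialpubs_parse_error")
      date[i] <- as.Date(sprintf("%s-%02d-%02d", parts[3], m, as.integer(parts[2])))
      precision[i] <- "day"
    } else if (grepl("^[A-Za-z]+ \\d{4}$", s)) {
      parts <- strsplit(s, " +")[[1]]
      m <- .month_names[tolower(parts[1])]
      if (is.na(m)) abort(sprintf("unrecognized month in date: '%s'", s), "trialpubs_parse_error")
      date[i] <- as.Date(sprintf("%s-%02d-01", parts[2], m))
      precision[i] <- "month"
    } else {
      abort(sprintf("unrecognized date format: '%s'", s), "trialpubs_parse_error")
    }
  }
  data.frame(date = date, precision = precision, stringsAsFactors = FALSE)
}

# format a Date at a given precision, for serialization round trips
format_partial_date <- function(date, precision) {
  out <- rep(NA_character_, length(date))
  for (i in seq_along(date)) {
    if (is.na(date[i]) || precision[i] == "missing") next
    out[i] <- switch(precision[i],
      day = format(date[i], "%Y-%m-%d"),
      month = format(date[i], "%Y-%m"),
      year = format(date[i], "%Y")
    )
  }
  out
}
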