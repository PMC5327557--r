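# Month-precision date handling.
#
# Cancer registries commonly release diagnosis dates at month precision only,
# so every temporal comparison in this package is performed on a linear month
# index; the day of month, when a source supplies one, is kept solely for
# deterministic intra-month tie-breaking of "first occurrence".

#' Parse month-precision study dates
#'
#' Dates are accepted as ISO 8601 strings, either `"YYYY-MM-DD"` or the
#' month-precision form `"YYYY-MM"`.  The day component is optional
#' throughout the package because the gold-standard registry supplies
#' diagnosis dates at month precision.
#'
#' @param x Character vector of dates (`"YYYY-MM"` or `"YYYY-MM-DD"`).
#'   `NA` elements are propagated.
#' @return A data.frame with integer columns `year`, `month` and `day`
#'   (`day` is `NA` for month-precision input).
#' @examples
#' parse_study_date(c("2006-02", "2006-02-14"))
#' @export
parse_study_date <- function(x) {
  x <- as.character(x)
  out <- data.frame(year = rep(NA_integer_, length(x)),
                    month = rep(NA_integer_, length(x)),
                    day = rep(NA_integer_, length(x)))
  ok_na <- is.na(x) | !nzchar(x)
  full <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  ym <- grepl("^\\d{4}-\\d{2}$", x)
  bad <- !(ok_na | full | ym)
  if (any(bad)) {
    stop("malformed study date(s): ",
         paste(utils::head(unique(x[bad]), 5L), collapse = ", "),
         call. = FALSE)
  }
  out$year[full | ym] <- as.integer(substr(x[full | ym], 1L, 4L))
  out$month[full | ym] <- as.integer(substr(x[full | ym], 6L, 7L))
  out$day[full] <- as.integer(substr(x[full], 9L, 10L))
  chk <- !is.na(out$month) & (out$month < 1L | out$month > 12L)
  if (any(chk)) {
    stop("month out of range in study date(s): ",
         paste(utils::head(unique(x[chk]), 5L), collapse = ", "),
         call. = FALSE)
  }
  dim <- c(31L, 29L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  chkd <- !is.na(out$day) & (out$day < 1L | out$day > dim[out$month])
  if (any(chkd)) {
    stop("day invalid for month in study date(s): ",
         paste(utils::head(unique(x[chkd]), 5L), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Linear month index of a study date
#'
#' Maps a calendar month to `12 * year + (month - 1)`, a strictly increasing
#' integer index on which all temporal matching is performed.  The day of
#' month is ignored.
#'
#' @param x Character vector of dates (`"YYYY-MM"` or `"YYYY-MM-DD"`), or an
#'   integer/numeric year vector when `month` is supplied.
#' @param month Optional integer month (1-12) when `x` is a year.
#' @return Integer vector of month indices.
#' @examples
#' month_index("2006-02")          # 24073
#' month_index(2010, 12) - month_index(2009, 12)  # 12
#' @export
month_index <- function(x, month = NULL) {
  if (!is.null(month)) {
    year <- as.integer(x)
    month <- as.integer(month)
    if (any(!is.na(month) & (month < 1L | month > 12L))) {
      stop("month out of range", call. = FALSE)
    }
    return(12L * year + (month - 1L))
  }
  p <- parse_study_date(x)
  12L * p$year + (p$month - 1L)
}

#' Difference between two study dates in whole calendar months
#'
#' @param a,b Character date vectors (`"YYYY-MM"` or `"YYYY-MM-DD"`).
#' @return Integer vector `month_index(a) - month_index(b)`.
#' @export
month_diff <- function(a, b) month_index(a) - month_index(b)

#' Format a month index back to "YYYY-MM"
#'
#' @param idx Integer month index as returned by [month_index()].
#' @return Character vector `"YYYY-MM"`.
#' @export
format_month <- function(idx) {
  idx <- as.integer(idx)
  sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
}

# Day of month (NA for month-precision dates); internal helper.
date_day <- function(x) parse_study_date(x)$day

# Ordering key used for "first occurrence" selection: primary month index,
# then dated-before-undated within the month, then day, then slot order.
# Returns the index of the earliest element.
first_occurrence <- function(dates, slot = seq_along(dates)) {
  if (length(dates) == 0L) return(integer(0))
  p <- parse_study_date(dates)
  mi <- 12L * p$year + (p$month - 1L)
  has_day <- !is.na(p$day)
  day <- ifelse(has_day, p$day, 99L)  # undated sorts after any dated day
  order(mi, !has_day, day, slot)[1L]
}
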