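#' Daily time series
#'
#' A `daily_series` is a data frame with a `date` column (contiguous calendar
#' days, strictly increasing, no gaps) and a numeric `value` column. It is the
#' common container for daily death counts, population, mortality rates
#' (1/100,000), relative mortality (%), and thermal-index values (degrees C).
#'
#' @param dates Date vector, one entry per calendar day, contiguous.
#' @param values numeric vector, same length as `dates`. Finite, except where
#'   an operation explicitly documents a missing-value marker (`NA`).
#' @param age_group optional age-group label (`"all"`, `"lt65"`, `"65_74"`,
#'   `"ge75"`, `"ge65"`), stored as an attribute.
#' @param units optional unit string stored as an attribute.
#' @param allow_na allow `NA` values (used for sub-daily aggregation where
#'   incomplete days are marked missing).
#'
#' @return A data frame of class `daily_series` with columns `date`, `value`.
#' @export
daily_series <- function(dates, values, age_group = NULL, units = NULL,
                         allow_na = FALSE) {
  dates <- as.Date(dates)
  if (length(dates) == 0L) stop("empty daily series", call. = FALSE)
  if (length(dates) != length(values)) {
    stop("dates and values differ in length", call. = FALSE)
  }
  if (anyNA(dates)) stop("dates contain NA", call. = FALSE)
  d <- diff(as.numeric(dates))
  if (length(d) && any(d != 1)) {
    bad <- which(d != 1)[1]
    stop(sprintf("dates must be contiguous calendar days; gap after %s",
                 format(dates[bad])), call. = FALSE)
  }
  values <- as.numeric(values)
  if (!allow_na && (anyNA(values) || any(!is.finite(values)))) {
    stop("values must be finite", call. = FALSE)
  }
  out <- data.frame(date = dates, value = values)
  class(out) <- c("daily_series", "data.frame")
  attr(out, "age_group") <- age_group
  attr(out, "units") <- units
  out
}

#' @rdname daily_series
#' @param x object to test or convert.
#' @export
is_daily_series <- function(x) inherits(x, "daily_series")

#' @rdname daily_series
#' @export
as_daily_series <- function(x, age_group = NULL, units = NULL,
                            allow_na = FALSE) {
  if (is_daily_series(x)) return(x)
  if (!is.data.frame(x) || !all(c("date", "value") %in% names(x))) {
    stop("need a data frame with 'date' and 'value' columns", call. = FALSE)
  }
  daily_series(x$date, x$value, age_group = age_group, units = units,
               allow_na = allow_na)
}

#' @export
print.daily_series <- function(x, ...) {
  ag <- attr(x, "age_group")
  un <- attr(x, "units")
  cat(sprintf("<daily_series> %d days: %s .. %s%s%s\n",
              nrow(x), format(min(x$date)), format(max(x$date)),
              if (!is.null(ag)) paste0(", age group ", ag) else "",
              if (!is.null(un)) paste0(" [", un, "]") else ""))
  invisible(x)
}

# Restrict two daily series to their common date range; errors when disjoint.
align_series <- function(a, b, what = c("a", "b")) {
  lo <- max(min(a$date), min(b$date))
  hi <- min(max(a$date), max(b$date))
  if (lo > hi) {
    stop(sprintf("series '%s' (%s..%s) and '%s' (%s..%s) do not overlap",
                 what[1], format(min(a$date)), format(max(a$date)),
                 what[2], format(min(b$date)), format(max(b$date))),
         call. = FALSE)
  }
  list(a = a[a$date >= lo & a$date <= hi, , drop = FALSE],
       b = b[b$date >= lo & b$date <= hi, , drop = FALSE])
}
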