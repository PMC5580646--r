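DEFAULT_LEVELS <- c(0.01, 0.025, 0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95,
                    0.975, 0.99)

#' Percentile breakpoints of a thermal-index distribution
#'
#' Empirical quantiles of the index at the given probability levels, computed
#' over the whole study period. The 11 default levels (1, 2.5, 5, 10, 25, 50,
#' 75, 90, 95, 97.5, 99%) define 12 categories. Sub-period analyses reuse the
#' whole-period breakpoints.
#'
#' @param index a [thermal_index_series()] or numeric vector.
#' @param levels probability levels in (0, 1), strictly increasing.
#' @param type quantile rule passed to [stats::quantile()] (default 7, linear
#'   interpolation of order statistics).
#' @return object of class `percentile_breaks` with fields `levels`,
#'   `breakpoints`, `data_min`, `data_max`, `n`, `reference_period`.
#' @export
percentile_breaks <- function(index, levels = DEFAULT_LEVELS, type = 7) {
  if (is.data.frame(index)) {
    x <- index$value
    ref <- range(index$date)
  } else {
    x <- as.numeric(index)
    ref <- NULL
  }
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("empty index series", call. = FALSE)
  if (is.unsorted(levels, strictly = TRUE) || any(levels <= 0) || any(levels >= 1)) {
    stop("levels must be strictly increasing and inside (0, 1)", call. = FALSE)
  }
  if (length(x) < 1 / min(levels)) {
    warning(sprintf("only %d observations for a smallest level of %g; extreme breakpoints are unstable",
                    length(x), min(levels)), call. = FALSE)
  }
  bp <- unname(stats::quantile(x, probs = levels, type = type))
  out <- list(levels = levels, breakpoints = bp,
              data_min = min(x), data_max = max(x), n = length(x),
              reference_period = ref)
  if (any(diff(bp) == 0)) {
    out$degenerate <- TRUE
    warning("degenerate categories: some breakpoints coincide", call. = FALSE)
  } else {
    out$degenerate <- FALSE
  }
  class(out) <- "percentile_breaks"
  out
}

#' @export
print.percentile_breaks <- function(x, ...) {
  cat(sprintf("<percentile_breaks> %d levels -> %d categories, data range %.1f..%.1f (n = %d)\n",
              length(x$levels), length(x$levels) + 1L, x$data_min, x$data_max, x$n))
  print(data.frame(level = x$levels, breakpoint = x$breakpoints))
  invisible(x)
}

#' Classify index values into percentile categories
#'
#' Right-closed intervals: category 1 is `(-Inf, b1]`, category k is
#' `(b_{k-1}, b_k]`, category 12 is `(b_11, +Inf)`. Ties at a breakpoint fall
#' into the lower category. Values outside the reference data range are still
#' classified (needed when sub-periods reuse whole-period breakpoints).
#'
#' @param values numeric vector (no NaN/NA).
#' @param breaks a [percentile_breaks()].
#' @return integer vector of category ids in `1 .. length(levels) + 1`.
#' @export
classify_index <- function(values, breaks) {
  stopifnot(inherits(breaks, "percentile_breaks"))
  if (anyNA(values) || any(!is.finite(values))) {
    stop("cannot classify missing or non-finite values", call. = FALSE)
  }
  findInterval(values, breaks$breakpoints, left.open = TRUE) + 1L
}

# Human-readable category interval labels, tiling [data_min, data_max].
category_ranges <- function(breaks) {
  lo <- c(breaks$data_min, breaks$breakpoints)
  hi <- c(breaks$breakpoints, breaks$data_max)
  data.frame(category = seq_along(lo), range_low = lo, range_high = hi)
}

# Percentile interval labels like "99-100".
category_labels <- function(breaks) {
  pct <- c(0, breaks$levels * 100, 100)
  sprintf("%s-%s", formatC(pct[-length(pct)], format = "fg"),
          formatC(pct[-1], format = "fg"))
}

t_ci <- function(x, conf = 0.95) {
  n <- length(x)
  m <- mean(x)
  if (n < 2L) return(c(mean = m, lo = NA_real_, hi = NA_real_))
  half <- stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(x) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half)
}

#' Category means of relative mortality with 95% confidence intervals
#'
#' Classifies the exposure of each pair into a percentile category and reports
#' per category the number of days, the arithmetic mean response and a plain
#' t-interval (`mean +/- t_{0.975, n-1} sd / sqrt(n)`). Empty categories get a
#' row with `n = 0` and undefined statistics.
#'
#' @param pairs an `exposure_pairs` data frame from [make_pairs()].
#' @param breaks a [percentile_breaks()].
#' @param conf confidence level.
#' @return data frame of class `category_summary`: `category`, `percentiles`,
#'   `range_low`, `range_high`, `n`, `mean`, `ci_low`, `ci_high`, `age_group`.
#' @export
category_summary <- function(pairs, breaks, conf = 0.95) {
  stopifnot(inherits(breaks, "percentile_breaks"))
  ncat <- length(breaks$levels) + 1L
  cat_id <- classify_index(pairs$exposure, breaks)
  rows <- lapply(seq_len(ncat), function(k) {
    y <- pairs$response[cat_id == k]
    ci <- if (length(y)) t_ci(y, conf) else c(mean = NA_real_, lo = NA_real_, hi = NA_real_)
    data.frame(category = k, n = length(y), mean = ci[["mean"]],
               ci_low = ci[["lo"]], ci_high = ci[["hi"]])
  })
  out <- do.call(rbind, rows)
  rng <- category_ranges(breaks)
  out <- cbind(percentiles = category_labels(breaks),
               rng[match(out$category, rng$category), c("range_low", "range_high")],
               out)
  out$age_group <- pairs$age_group[1] %||% NA_character_
  rownames(out) <- NULL
  class(out) <- c("category_summary", "data.frame")
  out
}

#' Linear time trend of relative mortality within each category
#'
#' OLS of the response on elapsed decades, restricted to the pairs falling in
#' each percentile category; slope in % per decade with 95% CI, two-sided
#' p-value, and significance stars (* p < 0.05, ** p < 0.01, *** p < 0.001).
#' Categories with fewer than 3 pairs get an undefined, flagged trend.
#'
#' @inheritParams category_summary
#' @return data frame of class `category_trend`: `category`, `n`, `trend`,
#'   `ci_low`, `ci_high`, `p_value`, `stars`.
#' @export
category_trend <- function(pairs, breaks) {
  stopifnot(inherits(breaks, "percentile_breaks"))
  ncat <- length(breaks$levels) + 1L
  cat_id <- classify_index(pairs$exposure, breaks)
  origin <- min(pairs$date)
  rows <- lapply(seq_len(ncat), function(k) {
    sel <- cat_id == k
    if (sum(sel) < 3L) {
      return(data.frame(category = k, n = sum(sel), trend = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_, stars = "", defined = FALSE))
    }
    tr <- linear_trend(daily_series_unchecked(pairs$date[sel],
                                              pairs$response[sel]))
    data.frame(category = k, n = sum(sel), trend = tr$slope,
               ci_low = tr$ci_low, ci_high = tr$ci_high,
               p_value = tr$p_value, stars = stars_for_p(tr$p_value),
               defined = TRUE)
  })
  out <- do.call(rbind, rows)
  out$age_group <- pairs$age_group[1] %||% NA_character_
  class(out) <- c("category_trend", "data.frame")
  out
}

# Pairs within a category are not contiguous days; bypass the contiguity
# check but keep the date/value contract for the trend fit.
daily_series_unchecked <- function(dates, values) {
  out <- data.frame(date = as.Date(dates), value = as.numeric(values))
  class(out) <- c("daily_series", "data.frame")
  out
}

#' Sub-period comparison of category means (Welch t-test)
#'
#' Splits the pairs into two sub-periods (defaults: 1972-1992 and 1994-2014,
#' the intervening year excluded) and reports per category each sub-period's
#' mean with 95% CI, the Welch two-sample t statistic and two-sided p-value
#' (Welch-Satterthwaite degrees of freedom), significance stars, and
#' Shapiro-Wilk normality p-values per sub-period (deterministically thinned
#' to at most 5000 points when larger).
#'
#' @inheritParams category_summary
#' @param period_a,period_b length-2 vectors of dates (start, end).
#' @return data frame of class `subperiod_comparison`: per category `n_a`,
#'   `mean_a`, `ci_low_a`, `ci_high_a`, same for `b`, `welch_t`, `welch_df`,
#'   `welch_p`, `stars`, `shapiro_p_a`, `shapiro_p_b`.
#' @export
subperiod_compare <- function(pairs, breaks,
                              period_a = c("1972-01-01", "1992-12-31"),
                              period_b = c("1994-01-01", "2014-12-31"),
                              conf = 0.95) {
  stopifnot(inherits(breaks, "percentile_breaks"))
  period_a <- as.Date(period_a)
  period_b <- as.Date(period_b)
  ncat <- length(breaks$levels) + 1L
  cat_id <- classify_index(pairs$exposure, breaks)
  in_a <- pairs$date >= period_a[1] & pairs$date <= period_a[2]
  in_b <- pairs$date >= period_b[1] & pairs$date <= period_b[2]
  if (!any(in_a) || !any(in_b)) {
    stop("a sub-period contains no pairs", call. = FALSE)
  }
  shapiro_p <- function(y) {
    if (length(y) < 3L) return(NA_real_)
    if (length(y) > 5000L) y <- y[round(seq(1L, length(y), length.out = 5000L))]
    if (stats::sd(y) == 0) return(NA_real_)
    stats::shapiro.test(y)$p.value
  }
  rows <- lapply(seq_len(ncat), function(k) {
    ya <- pairs$response[cat_id == k & in_a]
    yb <- pairs$response[cat_id == k & in_b]
    ca <- if (length(ya)) t_ci(ya, conf) else c(mean = NA_real_, lo = NA_real_, hi = NA_real_)
    cb <- if (length(yb)) t_ci(yb, conf) else c(mean = NA_real_, lo = NA_real_, hi = NA_real_)
    if (length(ya) >= 2L && length(yb) >= 2L &&
        (stats::sd(ya) > 0 || stats::sd(yb) > 0)) {
      tt <- stats::t.test(ya, yb, var.equal = FALSE)
      wt <- unname(tt$statistic)
      wdf <- unname(tt$parameter)
      wp <- tt$p.value
    } else {
      wt <- NA_real_; wdf <- NA_real_; wp <- NA_real_
    }
    data.frame(category = k,
               n_a = length(ya), mean_a = ca[["mean"]],
               ci_low_a = ca[["lo"]], ci_high_a = ca[["hi"]],
               n_b = length(yb), mean_b = cb[["mean"]],
               ci_low_b = cb[["lo"]], ci_high_b = cb[["hi"]],
               welch_t = wt, welch_df = wdf, welch_p = wp,
               stars = stars_for_p(wp),
               shapiro_p_a = shapiro_p(ya), shapiro_p_b = shapiro_p(yb),
               defined = length(ya) >= 2L && length(yb) >= 2L)
  })
  out <- do.call(rbind, rows)
  out$age_group <- pairs$age_group[1] %||% NA_character_
  class(out) <- c("subperiod_comparison", "data.frame")
  out
}

#' Combined category table (the study's table shape)
#'
#' Joins [category_summary()], [category_trend()] and [subperiod_compare()]
#' into one table per age group: percentile interval, index range, whole-period
#' mean (95% CI), trend (%/decade) with stars, sub-period means, and the Welch
#' test stars.
#'
#' @inheritParams subperiod_compare
#' @return data frame of class `category_table`.
#' @export
category_table <- function(pairs, breaks,
                           period_a = c("1972-01-01", "1992-12-31"),
                           period_b = c("1994-01-01", "2014-12-31")) {
  cs <- category_summary(pairs, breaks)
  ct <- category_trend(pairs, breaks)
  sp <- subperiod_compare(pairs, breaks, period_a, period_b)
  out <- data.frame(
    age_group = cs$age_group,
    percentiles = cs$percentiles,
    range_low = cs$range_low, range_high = cs$range_high,
    n = cs$n, mean = cs$mean, ci_low = cs$ci_low, ci_high = cs$ci_high,
    trend = ct$trend, trend_ci_low = ct$ci_low, trend_ci_high = ct$ci_high,
    trend_p = ct$p_value, trend_stars = ct$stars,
    n_a = sp$n_a, mean_a = sp$mean_a, ci_low_a = sp$ci_low_a, ci_high_a = sp$ci_high_a,
    n_b = sp$n_b, mean_b = sp$mean_b, ci_low_b = sp$ci_low_b, ci_high_b = sp$ci_high_b,
    welch_p = sp$welch_p, welch_stars = sp$stars,
    shapiro_p_a = sp$shapiro_p_a, shapiro_p_b = sp$shapiro_p_b)
  class(out) <- c("category_table", "data.frame")
  out
}

#' Format a category table as a markdown report
#'
#' @param tbl a [category_table()] (or a list of them, one per age group).
#' @param digits digits for means and CIs.
#' @return character vector of markdown lines.
#' @export
format_category_report <- function(tbl, digits = 1) {
  tbls <- if (inherits(tbl, "category_table")) list(tbl) else tbl
  fmt <- function(x) ifelse(is.na(x), "-", formatC(x, format = "f", digits = digits))
  lines <- c("| Age group | Percentiles | Index range (C) | Mean RM % (95% CI) | Trend %/decade (95% CI) | | RM % period A | RM % period B | t-test |",
             "|---|---|---|---|---|---|---|---|---|")
  for (tt in tbls) {
    lines <- c(lines, sprintf(
      "| %s | %s | %s, %s | %s (%s, %s) | %s (%s, %s) | %s | %s (%s, %s) | %s (%s, %s) | %s |",
      tt$age_group, tt$percentiles, fmt(tt$range_low), fmt(tt$range_high),
      fmt(tt$mean), fmt(tt$ci_low), fmt(tt$ci_high),
      fmt(tt$trend), fmt(tt$trend_ci_low), fmt(tt$trend_ci_high), tt$trend_stars,
      fmt(tt$mean_a), fmt(tt$ci_low_a), fmt(tt$ci_high_a),
      fmt(tt$mean_b), fmt(tt$ci_low_b), fmt(tt$ci_high_b), tt$welch_stars))
  }
  c(lines, "",
    "Significance: * p < 0.05, ** p < 0.01, *** p < 0.001.",
    "No multiple-testing correction is applied across categories or age groups.")
}
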