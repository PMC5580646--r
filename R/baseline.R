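#' Interpolate annual population to daily values
#'
#' Piecewise-linear interpolation between annual anchor dates (mid-year by
#' default); outside the first/last anchor the endpoint values are held flat.
#'
#' @param population annual population table with columns `year`, `population`
#'   and optionally `age_group`.
#' @param age_group group to extract when the table is long-format.
#' @param dates Date vector at which to evaluate; defaults to Jan 1 of the
#'   first year through Dec 31 of the last year.
#' @param anchor_doy day of year used as the annual anchor (default 182,
#'   i.e. about July 1).
#' @return a [daily_series()] of persons.
#' @export
interpolate_population <- function(population, age_group = NULL, dates = NULL,
                                   anchor_doy = 182) {
  pop <- population
  if (!is.null(age_group) && "age_group" %in% names(pop)) {
    pop <- pop[pop$age_group == age_group, , drop = FALSE]
  }
  if (!all(c("year", "population") %in% names(pop))) {
    stop("population table needs columns 'year' and 'population'", call. = FALSE)
  }
  pop <- pop[order(pop$year), , drop = FALSE]
  if (nrow(pop) < 2L) {
    stop("at least two annual population values are required for interpolation",
         call. = FALSE)
  }
  if (any(pop$population <= 0)) stop("population must be > 0", call. = FALSE)
  anchors <- as.Date(sprintf("%d-01-01", pop$year)) + (anchor_doy - 1)
  if (is.null(dates)) {
    dates <- seq(as.Date(sprintf("%d-01-01", min(pop$year))),
                 as.Date(sprintf("%d-12-31", max(pop$year))), by = "day")
  }
  vals <- stats::approx(as.numeric(anchors), pop$population,
                        xout = as.numeric(dates), rule = 2)$y
  daily_series(dates, vals, age_group = age_group, units = "persons")
}

#' Daily mortality rate per 100,000
#'
#' @param deaths a [daily_series()] of daily death counts.
#' @param population a [daily_series()] of persons (strictly positive).
#' @return a [daily_series()] of deaths per 100,000 per day over the common
#'   date range.
#' @export
daily_rate <- function(deaths, population) {
  deaths <- as_daily_series(deaths)
  population <- as_daily_series(population)
  al <- align_series(deaths, population, c("deaths", "population"))
  if (any(al$b$value <= 0)) {
    stop("population must be strictly positive", call. = FALSE)
  }
  daily_series(al$a$date, al$a$value / al$b$value * 1e5,
               age_group = attr(deaths, "age_group"), units = "per 100,000")
}

#' Gaussian smoothing kernel
#'
#' Centered, truncated, renormalized Gaussian filter used to compute expected
#' (baseline) mortality. Weights are proportional to `exp(-offset^2/(2 sigma^2))`
#' on offsets `-(width-1)/2 .. +(width-1)/2` and sum to one.
#'
#' The default is a 365-day window with `sigma = 365/12` days. The sigma
#' controls the trade-off between noise suppression and preservation of the
#' seasonal cycle in the baseline: the filter's gain at the annual harmonic is
#' `exp(-(2 pi sigma / 365.25)^2 / 2)`, about 0.87 at the default, so the
#' baseline follows the seasonal cycle while day-to-day variability is smoothed
#' out.
#'
#' @param width total filter width in days (odd, >= 3).
#' @param sigma Gaussian standard deviation in days (> 0).
#' @return object of class `gaussian_kernel` with fields `half_width`, `sigma`,
#'   `weights`.
#' @export
gaussian_kernel <- function(width = 365, sigma = 365 / 12) {
  if (length(width) != 1L || width < 3 || width %% 2 == 0) {
    stop("kernel width must be an odd integer >= 3 (a centered kernel)",
         call. = FALSE)
  }
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  hw <- (width - 1) / 2
  off <- -hw:hw
  w <- exp(-off^2 / (2 * sigma^2))
  w <- w / sum(w)
  out <- list(half_width = hw, sigma = sigma, weights = w)
  class(out) <- "gaussian_kernel"
  out
}

#' @export
print.gaussian_kernel <- function(x, ...) {
  cat(sprintf("<gaussian_kernel> width %d days, sigma %.2f days\n",
              2 * x$half_width + 1, x$sigma))
  invisible(x)
}

#' Expected (baseline) mortality by Gaussian smoothing
#'
#' Centered convolution of the daily mortality series with a Gaussian kernel.
#' The baseline retains the seasonal cycle but removes day-to-day variability
#' and, being a symmetric filter, reproduces linear trends exactly in the
#' interior. The first and last `half_width` days are dropped (no renormalized
#' partial windows), so the smoothing shortens the series from both ends.
#'
#' @param series a [daily_series()] (typically the daily rate per 100,000).
#' @param kernel a [gaussian_kernel()].
#' @return a [daily_series()] on the retained (shortened) date range.
#' @export
expected_mortality <- function(series, kernel = gaussian_kernel()) {
  series <- as_daily_series(series)
  stopifnot(inherits(kernel, "gaussian_kernel"))
  hw <- kernel$half_width
  n <- nrow(series)
  if (n <= 2 * hw + 1) {
    stop(sprintf("series length (%d) must exceed kernel width (%d)",
                 n, 2 * hw + 1), call. = FALSE)
  }
  sm <- stats::filter(series$value, kernel$weights, method = "convolution",
                      sides = 2)
  keep <- (hw + 1):(n - hw)
  daily_series(series$date[keep], as.numeric(sm[keep]),
               age_group = attr(series, "age_group"),
               units = attr(series, "units"))
}

#' Relative mortality (% deviation from expected)
#'
#' `rm(d) = 100 * (observed(d) - expected(d)) / expected(d)`, computed on the
#' common date range. By construction the series is stationary: the seasonal
#' cycle and long-term trends of the observed mortality are divided out by the
#' smoothed baseline.
#'
#' @param observed a [daily_series()] of observed mortality (rate or counts).
#' @param expected a [daily_series()] of expected mortality from
#'   [expected_mortality()] (strictly positive).
#' @return a [daily_series()] of percent deviations, with attribute
#'   `units = "%"`.
#' @export
relative_mortality <- function(observed, expected) {
  observed <- as_daily_series(observed)
  expected <- as_daily_series(expected)
  al <- align_series(observed, expected, c("observed", "expected"))
  if (any(al$b$value <= 0)) {
    stop("expected mortality must be strictly positive", call. = FALSE)
  }
  daily_series(al$a$date, 100 * (al$a$value - al$b$value) / al$b$value,
               age_group = attr(observed, "age_group"), units = "%")
}

#' Trim a daily series to full calendar years
#'
#' Retains January 1 through December 31 of the first and last fully covered
#' calendar years, so analyses run on complete years only.
#'
#' @param series a [daily_series()].
#' @return a [daily_series()] covering complete calendar years.
#' @export
trim_to_full_years <- function(series) {
  series <- as_daily_series(series, allow_na = TRUE)
  yrs <- as.integer(format(range(series$date), "%Y"))
  candidates <- yrs[1]:yrs[2]
  ok <- vapply(candidates, function(y) {
    as.Date(sprintf("%d-01-01", y)) >= min(series$date) &&
      as.Date(sprintf("%d-12-31", y)) <= max(series$date)
  }, logical(1))
  if (!any(ok)) stop("series contains no complete calendar year", call. = FALSE)
  lo <- as.Date(sprintf("%d-01-01", min(candidates[ok])))
  hi <- as.Date(sprintf("%d-12-31", max(candidates[ok])))
  out <- series[series$date >= lo & series$date <= hi, , drop = FALSE]
  daily_series(out$date, out$value, age_group = attr(series, "age_group"),
               units = attr(series, "units"), allow_na = TRUE)
}

#' Linear time trend per decade
#'
#' Ordinary least squares of the series values on elapsed decades (one decade
#' = 3652.5 days), with a symmetric 95% confidence interval from the
#' t-distribution and a two-sided p-value.
#'
#' @param series a [daily_series()] (or data frame with `date`, `value`).
#' @param conf confidence level (default 0.95).
#' @return list of class `trend_estimate`: `slope` (units per decade),
#'   `ci_low`, `ci_high`, `p_value`, `se`, `n`.
#' @export
linear_trend <- function(series, conf = 0.95) {
  series <- as_daily_series(series, allow_na = TRUE)
  keep <- is.finite(series$value)
  x <- elapsed_decades(series$date[keep], origin = min(series$date))
  y <- series$value[keep]
  if (length(y) < 3L) stop("need at least 3 points for a trend", call. = FALSE)
  if (diff(range(x)) == 0) stop("constant time axis", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # a noise-free line triggers the "essentially perfect fit" warning; that
  # case is handled explicitly below
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["x", "Estimate"]
  se <- sm["x", "Std. Error"]
  df <- fit$df.residual
  if (!is.finite(se) || se < 1e-12 * max(1, abs(slope))) {
    # Degenerate (noise-free) input: exact line or exact constant.
    p <- if (abs(slope) < 1e-12) 1 else 0
    ci <- c(slope, slope)
  } else {
    tcrit <- stats::qt(1 - (1 - conf) / 2, df)
    ci <- slope + c(-1, 1) * tcrit * se
    p <- 2 * stats::pt(abs(slope / se), df, lower.tail = FALSE)
  }
  out <- list(slope = slope, ci_low = ci[1], ci_high = ci[2],
              p_value = p, se = se, n = length(y))
  class(out) <- "trend_estimate"
  out
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat(sprintf("trend %.4g per decade (95%% CI %.4g, %.4g), p = %.3g, n = %d\n",
              x$slope, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}
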