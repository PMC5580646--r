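#' Smooth exposure-response curve (penalized regression spline)
#'
#' Fits a penalized thin-plate regression spline of relative mortality on the
#' thermal index (a generalized additive model with Gaussian errors) and
#' returns the fitted curve with a pointwise 95% confidence band on an evenly
#' spaced grid over the observed exposure range. The smoothing parameter is
#' selected by GCV (default) or REML; the penalty's null space contains linear
#' functions, so as the smoothing parameter grows the fit approaches the
#' ordinary least-squares line.
#'
#' @param pairs an `exposure_pairs` data frame from [make_pairs()] (columns
#'   `exposure`, `response`).
#' @param basis_dim spline basis dimension `k` (default 10).
#' @param criterion smoothing-parameter criterion, `"GCV"` or `"REML"`.
#' @param sp optional fixed smoothing parameter overriding the criterion
#'   (`Inf`-like large values give the penalized limit, i.e. the OLS line).
#' @param grid_n number of grid points.
#' @param conf confidence level of the pointwise band.
#' @param period optional period label stored on the result.
#' @return object of class `curve_estimate`: data frame `grid`, `fit`,
#'   `band_low`, `band_high`, with attributes `effective_df`,
#'   `smoothing_parameter`, `age_group`, `period`, and the fitted `gam` model.
#' @export
fit_curve <- function(pairs, basis_dim = 10, criterion = c("GCV", "REML"),
                      sp = NULL, grid_n = 200, conf = 0.95, period = NULL) {
  criterion <- match.arg(criterion)
  x <- pairs$exposure
  y <- pairs$response
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < basis_dim + 5) {
    stop(sprintf("need at least basis_dim + 5 = %d pairs, have %d",
                 basis_dim + 5, length(x)), call. = FALSE)
  }
  if (diff(range(x)) == 0) stop("exposure is constant; no curve to fit", call. = FALSE)
  if (length(unique(x)) < basis_dim) {
    stop(sprintf("rank deficiency: fewer distinct exposure values than basis_dim = %d",
                 basis_dim), call. = FALSE)
  }
  method <- if (criterion == "GCV") "GCV.Cp" else "REML"
  dat <- data.frame(x = x, y = y)
  fit <- mgcv::gam(y ~ s(x, k = basis_dim, bs = "tp"), data = dat,
                   method = method, sp = if (is.null(sp)) NULL else sp)
  grid <- seq(min(x), max(x), length.out = grid_n)
  pr <- mgcv::predict.gam(fit, newdata = data.frame(x = grid), se.fit = TRUE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- data.frame(grid = grid, fit = as.numeric(pr$fit),
                    band_low = as.numeric(pr$fit - z * pr$se.fit),
                    band_high = as.numeric(pr$fit + z * pr$se.fit))
  class(out) <- c("curve_estimate", "data.frame")
  attr(out, "effective_df") <- sum(fit$edf)
  attr(out, "smoothing_parameter") <- unname(fit$sp)
  attr(out, "age_group") <- pairs$age_group[1] %||% NA_character_
  attr(out, "period") <- period
  attr(out, "model") <- fit
  out
}

#' Evaluate a fitted curve at new exposure values
#'
#' Linear interpolation of the stored fit and band on the curve's grid; no
#' extrapolation outside the observed exposure range.
#'
#' @param curve a [fit_curve()] result.
#' @param x numeric exposure values inside the grid range.
#' @return data frame `x`, `fit`, `band_low`, `band_high`.
#' @export
evaluate_curve <- function(curve, x) {
  stopifnot(inherits(curve, "curve_estimate"))
  rng <- range(curve$grid)
  if (any(x < rng[1] | x > rng[2])) {
    stop(sprintf("x outside fitted exposure range %.3f..%.3f (no extrapolation)",
                 rng[1], rng[2]), call. = FALSE)
  }
  data.frame(
    x = x,
    fit = stats::approx(curve$grid, curve$fit, xout = x)$y,
    band_low = stats::approx(curve$grid, curve$band_low, xout = x)$y,
    band_high = stats::approx(curve$grid, curve$band_high, xout = x)$y)
}

#' @export
print.curve_estimate <- function(x, ...) {
  cat(sprintf("<curve_estimate> %d grid points over %.1f..%.1f, edf %.2f%s%s\n",
              nrow(x), min(x$grid), max(x$grid), attr(x, "effective_df"),
              if (!is.null(attr(x, "age_group"))) paste0(", age group ", attr(x, "age_group")) else "",
              if (!is.null(attr(x, "period"))) paste0(", period ", attr(x, "period")) else ""))
  invisible(x)
}
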