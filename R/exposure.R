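INDEX_KINDS <- c("tavg", "tmax", "tmin", "pet_daily_mean", "pet_06utc", "pet_12utc")

#' Thermal-index daily series
#'
#' A [daily_series()] of a thermal index in degrees C (air temperature or
#' precomputed physiologically equivalent temperature, PET), tagged with the
#' index kind and provenance. Values outside the plausible range -80..+60 C
#' trigger a warning (not an error).
#'
#' @param dates,values as in [daily_series()]; `NA` marks missing days.
#' @param index_kind one of `r paste(INDEX_KINDS, collapse = ", ")`.
#' @param provenance `"station"`, `"grid-average"` or `"precomputed"`.
#' @return a `thermal_index` / `daily_series` data frame.
#' @export
thermal_index_series <- function(dates, values, index_kind = "tavg",
                                 provenance = "station") {
  index_kind <- match.arg(index_kind, INDEX_KINDS)
  out <- daily_series(dates, values, units = "degC", allow_na = TRUE)
  finite <- out$value[is.finite(out$value)]
  if (length(finite) && (min(finite) < -80 || max(finite) > 60)) {
    warning(sprintf("thermal index values outside plausible range -80..60 C (%.1f..%.1f)",
                    min(finite), max(finite)), call. = FALSE)
  }
  attr(out, "index_kind") <- index_kind
  attr(out, "provenance") <- provenance
  class(out) <- c("thermal_index", class(out))
  out
}

#' Daily means from sub-daily observations
#'
#' Unweighted mean of each day's observations (e.g. the 8 synoptic 3-hourly
#' values). Days with fewer than `min_obs` observations are marked missing
#' (`NA`).
#'
#' @param subdaily data frame with columns `date`, `value` (and optionally
#'   `hour`).
#' @param min_obs minimum number of observations per retained day (default 6
#'   of the 8 three-hourly slots).
#' @param index_kind,provenance passed to [thermal_index_series()].
#' @return a [thermal_index_series()] of daily means.
#' @export
daily_mean_from_subdaily <- function(subdaily, min_obs = 6,
                                     index_kind = "tavg",
                                     provenance = "station") {
  if (!is.data.frame(subdaily) || nrow(subdaily) == 0L ||
      !all(c("date", "value") %in% names(subdaily))) {
    stop("need a non-empty data frame with 'date' and 'value' columns",
         call. = FALSE)
  }
  dts <- as.Date(subdaily$date)
  ok <- is.finite(subdaily$value)
  counts <- tapply(ok, dts, sum)
  means <- tapply(ifelse(ok, subdaily$value, NA_real_), dts, mean, na.rm = TRUE)
  days <- as.Date(names(counts))
  full <- seq(min(days), max(days), by = "day")
  v <- rep(NA_real_, length(full))
  idx <- match(days, full)
  v[idx] <- ifelse(counts >= min_obs, means, NA_real_)
  thermal_index_series(full, v, index_kind = index_kind,
                       provenance = provenance)
}

#' Spatial average over grid cells
#'
#' Unweighted per-day mean over the cells of a gridded thermal-index field.
#' All cells must cover exactly the same dates.
#'
#' @param cells either a data frame with columns `date`, `cell_id`, `value`,
#'   or a list of [daily_series()] objects.
#' @param index_kind passed to [thermal_index_series()].
#' @return a [thermal_index_series()] with provenance `"grid-average"`.
#' @export
spatial_average <- function(cells, index_kind = "tavg") {
  if (is.data.frame(cells)) {
    if (!all(c("date", "cell_id", "value") %in% names(cells))) {
      stop("cells data frame needs columns 'date', 'cell_id', 'value'",
           call. = FALSE)
    }
    split_cells <- split(cells[, c("date", "value")], cells$cell_id)
  } else if (is.list(cells) && length(cells) >= 1L) {
    split_cells <- lapply(cells, function(s) as_daily_series(s, allow_na = TRUE))
  } else {
    stop("need at least one cell series", call. = FALSE)
  }
  ref <- as.Date(split_cells[[1L]]$date)
  for (i in seq_along(split_cells)) {
    di <- as.Date(split_cells[[i]]$date)
    if (length(di) != length(ref) || any(di != ref)) {
      miss <- setdiff(format(ref), format(di))
      extra <- setdiff(format(di), format(ref))
      stop(sprintf("cell %s dates misaligned (missing: %s; extra: %s)",
                   names(split_cells)[i] %||% i,
                   paste(utils::head(miss, 3), collapse = ", "),
                   paste(utils::head(extra, 3), collapse = ", ")),
           call. = FALSE)
    }
  }
  m <- vapply(split_cells, function(s) as.numeric(s$value),
              numeric(length(ref)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(ref))
  thermal_index_series(ref, rowMeans(m), index_kind = index_kind,
                       provenance = "grid-average")
}

#' Exposure-response pairs
#'
#' Pairs a thermal-index exposure with a relative-mortality response under the
#' study's time-window designs:
#' \itemize{
#'   \item `lag_days = 1`, `window_days = 2` (the primary design): the
#'     response for exposure day `d` is the mean of relative mortality on day
#'     `d` and day `d + 1`, the exposure is the raw index on day `d`.
#'   \item `lag_days = 0`, `window_days = w > 1` (the 7- and 14-day designs):
#'     both response and exposure are trailing `w`-day means, labelled by the
#'     window's last day (or centered when `align = "center"`).
#'   \item `lag_days = 0`, `window_days = 1`: the raw aligned series.
#' }
#' Pairs that would require days outside the common coverage are dropped, as
#' are pairs with a missing exposure value.
#'
#' @param relmort a relative-mortality [daily_series()] (%).
#' @param index a [thermal_index_series()].
#' @param window_days response window length (>= 1).
#' @param lag_days 0 or 1.
#' @param align alignment of the lag-0 multi-day windows: `"trailing"`
#'   (default) or `"center"`.
#' @return data frame of class `exposure_pairs` with columns `date`,
#'   `exposure`, `response`, `window`, `lag`, `age_group`.
#' @export
make_pairs <- function(relmort, index, window_days = 2, lag_days = 1,
                       align = c("trailing", "center")) {
  align <- match.arg(align)
  relmort <- as_daily_series(relmort)
  index <- as_daily_series(index, allow_na = TRUE)
  if (window_days < 1) stop("window_days must be >= 1", call. = FALSE)
  if (!lag_days %in% c(0, 1)) stop("lag_days must be 0 or 1", call. = FALSE)
  al <- align_series(relmort, index, c("relative mortality", "index"))
  rm_v <- al$a$value
  ix_v <- al$b$value
  dts <- al$a$date
  n <- length(rm_v)
  if (window_days > n) {
    stop(sprintf("window (%d) exceeds series length (%d)", window_days, n),
         call. = FALSE)
  }
  if (lag_days == 1L) {
    # Forward window: response(d) = mean(rm[d .. d + window - 1]), exposure on d.
    if (window_days < 2) stop("lag_days = 1 requires window_days >= 2", call. = FALSE)
    keep <- seq_len(n - (window_days - 1L))
    resp <- rowMeans(vapply(0:(window_days - 1L),
                            function(k) rm_v[keep + k], numeric(length(keep))))
    expo <- ix_v[keep]
    date <- dts[keep]
  } else if (window_days == 1L) {
    resp <- rm_v
    expo <- ix_v
    date <- dts
  } else {
    w <- window_days
    resp <- as.numeric(stats::filter(rm_v, rep(1 / w, w), sides = 1))
    expo <- as.numeric(stats::filter(ix_v, rep(1 / w, w), sides = 1))
    keep <- w:n
    resp <- resp[keep]
    expo <- expo[keep]
    date <- if (align == "trailing") dts[keep] else dts[keep - floor((w - 1) / 2)]
  }
  ok <- is.finite(expo) & is.finite(resp)
  out <- data.frame(date = date[ok], exposure = expo[ok], response = resp[ok],
                    window = as.integer(window_days),
                    lag = as.integer(lag_days),
                    age_group = attr(relmort, "age_group") %||% NA_character_)
  class(out) <- c("exposure_pairs", "data.frame")
  attr(out, "index_kind") <- attr(index, "index_kind")
  out
}
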