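AGE_GROUPS <- c("lt65", "65_74", "ge75")

#' Configuration for the synthetic mortality/weather generator
#'
#' Builds and validates the configuration of the synthetic-data generator. The
#' generator emulates the statistical structure of a multi-decade daily
#' mortality study in a northern-European hospital district: Poisson daily
#' death counts with a winter-peaking seasonal cycle and a declining long-term
#' rate trend, a growing and ageing population, and a J-shaped excess-mortality
#' response to lagged daily mean temperature with configurable hot and cold
#' arms (optionally changing between sub-periods).
#'
#' Defaults describe a 1971-2015 study: population growing from 1.0 to 1.6
#' million with the 65+ share rising from 9.1% to 16.5%, a crude all-age
#' mortality rate near 2.2 per 100,000 per day declining about -0.116/decade
#' (about -2.1/decade among those 75+), and daily mean temperature around +5 C
#' with a 13 C seasonal amplitude, AR(1) day-to-day noise, and a +0.36 C/decade
#' warming trend.
#'
#' @param start_date,end_date calendar dates bounding the simulation.
#' @param n_gridcells number of exchangeable weather grid cells (>= 1).
#' @param temp_mean_annual annual-mean temperature (C).
#' @param temp_seasonal_amplitude seasonal half-range of temperature (C).
#' @param temp_trend warming trend (C per decade of 3652.5 days).
#' @param temp_ar1_coefficient AR(1) coefficient of daily noise, |phi| < 1.
#' @param temp_noise_sd innovation standard deviation of the AR(1) noise (C).
#' @param temp_peak_doy day of year of the warmest day (default mid-July).
#' @param temp_diurnal_amplitude amplitude of the 3-hourly diurnal cycle (C);
#'   the diurnal cycle always averages to zero over a day.
#' @param population_start,population_end total population at the first/last
#'   calendar year.
#' @param age_share_start,age_share_end named shares (`lt65`, `65_74`, `ge75`)
#'   of the population at the first/last year; interpolated linearly.
#' @param base_rate_start,base_rate_end named baseline mortality rates per age
#'   group (deaths per 100,000 per day) at the first/last day; interpolated
#'   linearly.
#' @param seasonal_mortality_amplitude fractional amplitude of the
#'   winter-peaking seasonal mortality cycle.
#' @param mortality_peak_doy day of year of peak mortality (default
#'   mid-January).
#' @param excess_curve_hot list of hot-arm specifications. Each element is a
#'   list with fields `threshold` (C), either `slope` (%/C above threshold,
#'   `form = "linear"`) or `excess` (constant % above threshold,
#'   `form = "step"`), optionally named per age group, and optional `start` /
#'   `end` dates. When several elements carry dates they must partition the
#'   simulated date range exactly (a step change between sub-periods).
#' @param excess_curve_cold single specification for the cold arm, a list with
#'   `threshold` (C) and `slope` (%/C below threshold, optionally per group),
#'   or `NULL` for no cold effect.
#' @param effect_lag_days integer >= 0; deaths on day d respond to temperature
#'   on day d - lag.
#' @param overdispersion variance inflation factor; 1 gives Poisson counts,
#'   > 1 negative-binomial counts with variance `overdispersion * mean`.
#' @param rng_seed integer seed; all randomness derives deterministically from
#'   it via per-stream sub-seeds.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(start_date = as.Date("1971-01-01"),
                             end_date = as.Date("2015-12-31"),
                             n_gridcells = 1L,
                             temp_mean_annual = 5,
                             temp_seasonal_amplitude = 13,
                             temp_trend = 0.36,
                             temp_ar1_coefficient = 0.8,
                             temp_noise_sd = 2.5,
                             temp_peak_doy = 196,
                             temp_diurnal_amplitude = 4,
                             population_start = 1.0e6,
                             population_end = 1.6e6,
                             age_share_start = c(lt65 = 0.909, "65_74" = 0.061, ge75 = 0.030),
                             age_share_end = c(lt65 = 0.835, "65_74" = 0.090, ge75 = 0.075),
                             base_rate_start = c(lt65 = 0.99, "65_74" = 11.5, ge75 = 28.7),
                             base_rate_end = c(lt65 = 0.25, "65_74" = 3.1, ge75 = 19.3),
                             seasonal_mortality_amplitude = 0.10,
                             mortality_peak_doy = 15,
                             excess_curve_hot = list(list(
                               threshold = 18,
                               slope = c(lt65 = 2.0, "65_74" = 2.5, ge75 = 3.5))),
                             excess_curve_cold = list(
                               threshold = -10,
                               slope = c(lt65 = 0.10, "65_74" = 0.15, ge75 = 0.30)),
                             effect_lag_days = 0L,
                             overdispersion = 1,
                             rng_seed = 1L) {
  cfg <- list(
    start_date = as.Date(start_date), end_date = as.Date(end_date),
    n_gridcells = as.integer(n_gridcells),
    temp_mean_annual = temp_mean_annual,
    temp_seasonal_amplitude = temp_seasonal_amplitude,
    temp_trend = temp_trend,
    temp_ar1_coefficient = temp_ar1_coefficient,
    temp_noise_sd = temp_noise_sd,
    temp_peak_doy = temp_peak_doy,
    temp_diurnal_amplitude = temp_diurnal_amplitude,
    population_start = population_start, population_end = population_end,
    age_share_start = age_share_start, age_share_end = age_share_end,
    base_rate_start = base_rate_start, base_rate_end = base_rate_end,
    seasonal_mortality_amplitude = seasonal_mortality_amplitude,
    mortality_peak_doy = mortality_peak_doy,
    excess_curve_hot = normalize_excess(excess_curve_hot, "hot"),
    excess_curve_cold = if (is.null(excess_curve_cold)) NULL else
      normalize_excess(list(excess_curve_cold), "cold")[[1L]],
    effect_lag_days = as.integer(effect_lag_days),
    overdispersion = overdispersion,
    rng_seed = as.integer(rng_seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

# Normalize an excess-curve specification: fill form, coerce per-group vectors.
normalize_excess <- function(specs, side) {
  lapply(specs, function(sp) {
    if (is.null(sp$threshold)) {
      stop(sprintf("excess_curve_%s: 'threshold' is required", side), call. = FALSE)
    }
    check_scalar(sp$threshold, paste0("excess_curve_", side, "$threshold"))
    form <- sp$form %||% if (!is.null(sp$excess)) "step" else "linear"
    if (!form %in% c("linear", "step")) {
      stop("excess curve 'form' must be 'linear' or 'step'", call. = FALSE)
    }
    coef <- if (form == "linear") sp$slope else sp$excess
    if (is.null(coef)) {
      stop(sprintf("excess_curve_%s: need 'slope' (linear) or 'excess' (step)", side),
           call. = FALSE)
    }
    if (is.null(names(coef))) coef <- stats::setNames(rep(coef[1], 3), AGE_GROUPS)
    if (!all(AGE_GROUPS %in% names(coef))) {
      stop(sprintf("excess_curve_%s coefficients must be named for groups %s",
                   side, paste(AGE_GROUPS, collapse = ", ")), call. = FALSE)
    }
    if (any(!is.finite(coef)) || any(coef < 0)) {
      stop(sprintf("excess_curve_%s coefficients must be finite and >= 0", side),
           call. = FALSE)
    }
    list(threshold = sp$threshold, form = form, coef = coef[AGE_GROUPS],
         start = if (!is.null(sp$start)) as.Date(sp$start) else NULL,
         end = if (!is.null(sp$end)) as.Date(sp$end) else NULL)
  })
}

validate_generator_config <- function(cfg) {
  if (is.na(cfg$start_date) || is.na(cfg$end_date)) {
    stop("field 'start_date'/'end_date' must be valid dates", call. = FALSE)
  }
  if (cfg$end_date <= cfg$start_date) {
    stop("field 'end_date' must be after 'start_date'", call. = FALSE)
  }
  for (f in c("temp_mean_annual", "temp_seasonal_amplitude", "temp_trend",
              "temp_ar1_coefficient", "temp_noise_sd", "temp_peak_doy",
              "temp_diurnal_amplitude", "population_start", "population_end",
              "seasonal_mortality_amplitude", "mortality_peak_doy",
              "overdispersion")) {
    check_scalar(cfg[[f]], f)
  }
  if (cfg$n_gridcells < 1L) stop("field 'n_gridcells' must be >= 1", call. = FALSE)
  if (cfg$temp_seasonal_amplitude < 0 || cfg$temp_noise_sd < 0 ||
      cfg$temp_diurnal_amplitude < 0 || cfg$seasonal_mortality_amplitude < 0) {
    stop("amplitudes and noise sd must be >= 0", call. = FALSE)
  }
  if (abs(cfg$temp_ar1_coefficient) >= 1) {
    stop("field 'temp_ar1_coefficient' must satisfy |phi| < 1", call. = FALSE)
  }
  if (cfg$population_start <= 0 || cfg$population_end <= 0) {
    stop("field 'population_start'/'population_end' must be > 0", call. = FALSE)
  }
  for (f in c("age_share_start", "age_share_end", "base_rate_start", "base_rate_end")) {
    v <- cfg[[f]]
    if (!all(AGE_GROUPS %in% names(v)) || any(!is.finite(v))) {
      stop(sprintf("field '%s' must be finite and named for groups %s",
                   f, paste(AGE_GROUPS, collapse = ", ")), call. = FALSE)
    }
    if (any(v <= 0)) stop(sprintf("field '%s' must be > 0", f), call. = FALSE)
  }
  for (f in c("age_share_start", "age_share_end")) {
    if (sum(cfg[[f]][AGE_GROUPS]) > 1 + 1e-8) {
      stop(sprintf("field '%s' shares exceed 1", f), call. = FALSE)
    }
  }
  if (cfg$effect_lag_days < 0L) stop("field 'effect_lag_days' must be >= 0", call. = FALSE)
  if (cfg$overdispersion < 1) stop("field 'overdispersion' must be >= 1", call. = FALSE)
  # Dated hot-arm specs must partition the simulated range exactly.
  dated <- Filter(function(sp) !is.null(sp$start) || !is.null(sp$end),
                  cfg$excess_curve_hot)
  if (length(dated) && length(dated) != length(cfg$excess_curve_hot)) {
    stop("either all or none of the hot excess specs may carry dates", call. = FALSE)
  }
  if (length(dated) > 0L) {
    ord <- order(vapply(dated, function(sp) as.numeric(sp$start), 0))
    dated <- dated[ord]
    if (dated[[1L]]$start != cfg$start_date ||
        dated[[length(dated)]]$end != cfg$end_date) {
      stop("dated hot excess specs must span start_date..end_date", call. = FALSE)
    }
    if (length(dated) > 1L) {
      for (i in seq_len(length(dated) - 1L)) {
        if (dated[[i + 1L]]$start != dated[[i]]$end + 1L) {
          stop("dated hot excess specs must partition the date range exactly",
               call. = FALSE)
        }
      }
    }
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> %s .. %s, %d grid cell(s), seed %d\n",
              format(x$start_date), format(x$end_date), x$n_gridcells, x$rng_seed))
  invisible(x)
}

# Injected excess-mortality curve g(T) in percent for one age group on given
# dates; zero on the neutral range between the cold and hot thresholds.
excess_g <- function(cfg, age_group, temp, dates) {
  g <- numeric(length(temp))
  for (sp in cfg$excess_curve_hot) {
    sel <- rep(TRUE, length(dates))
    if (!is.null(sp$start)) sel <- dates >= sp$start & dates <= sp$end
    co <- sp$coef[[age_group]]
    gh <- if (sp$form == "linear") co * pmax(temp - sp$threshold, 0) else
      co * (temp > sp$threshold)
    g[sel] <- g[sel] + gh[sel]
  }
  if (!is.null(cfg$excess_curve_cold)) {
    sp <- cfg$excess_curve_cold
    co <- sp$coef[[age_group]]
    g <- g + if (sp$form == "linear") co * pmax(sp$threshold - temp, 0) else
      co * (temp < sp$threshold)
  }
  g
}

#' Generate synthetic daily (and optionally 3-hourly) temperature
#'
#' Daily mean temperature is a seasonal cosine plus a linear warming trend plus
#' AR(1) noise, per grid cell; with several cells the cells are exchangeable
#' noise replicates and their spatial mean is returned alongside. The optional
#' 3-hourly series adds a diurnal cosine whose mean over the 8 synoptic hours
#' of a day is exactly the daily value.
#'
#' @param config a [generator_config()].
#' @param subdaily also generate a 3-hourly series for the spatial-mean cell.
#' @return A list of class `weather_field` with elements `daily` (a
#'   [daily_series()] of the spatial mean, degrees C), `cells` (data frame
#'   `date`, `cell_id`, `value`), and `subdaily` (`NULL` or data frame `date`,
#'   `hour`, `value`).
#' @export
generate_weather <- function(config, subdaily = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  dates <- seq(config$start_date, config$end_date, by = "day")
  n <- length(dates)
  doy <- day_of_year(dates)
  det <- config$temp_mean_annual +
    config$temp_seasonal_amplitude *
      cos(2 * pi * (doy - config$temp_peak_doy) / 365.25) +
    config$temp_trend * elapsed_decades(dates)
  phi <- config$temp_ar1_coefficient
  sd0 <- config$temp_noise_sd
  cells <- with_rng_seed(derive_seed(config$rng_seed, "weather"), {
    vapply(seq_len(config$n_gridcells), function(cell) {
      if (sd0 == 0) return(det)
      e0 <- stats::rnorm(1L, 0, sd0 / sqrt(1 - phi^2))
      innov <- stats::rnorm(n, 0, sd0)
      e <- as.numeric(stats::filter(innov, phi, method = "recursive", init = e0))
      det + e
    }, numeric(n))
  })
  daily_mean <- rowMeans(cells)
  cells_df <- data.frame(
    date = rep(dates, times = config$n_gridcells),
    cell_id = rep(seq_len(config$n_gridcells), each = n),
    value = as.numeric(cells))
  sub <- NULL
  if (subdaily) {
    hours <- seq(0, 21, by = 3)
    diurnal <- config$temp_diurnal_amplitude * cos(2 * pi * (hours - 14) / 24)
    diurnal <- diurnal - mean(diurnal)   # exact zero daily mean
    sub <- data.frame(
      date = rep(dates, each = length(hours)),
      hour = rep(hours, times = n),
      value = rep(daily_mean, each = length(hours)) + rep(diurnal, times = n))
  }
  out <- list(daily = daily_series(dates, daily_mean, units = "degC"),
              cells = cells_df, subdaily = sub)
  class(out) <- "weather_field"
  out
}

#' Generate an annual population table
#'
#' Total population is interpolated linearly between the configured endpoints,
#' one value per calendar year; age-group shares shift linearly between their
#' endpoint values (emulating an ageing population).
#'
#' @param config a [generator_config()].
#' @return data frame with columns `year`, `age_group`, `population`
#'   (age groups `lt65`, `65_74`, `ge75` plus their sum `all`).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  y0 <- as.integer(format(config$start_date, "%Y"))
  y1 <- as.integer(format(config$end_date, "%Y"))
  years <- y0:y1
  frac <- if (y1 > y0) (years - y0) / (y1 - y0) else rep(0, length(years))
  total <- config$population_start +
    frac * (config$population_end - config$population_start)
  rows <- lapply(AGE_GROUPS, function(g) {
    share <- config$age_share_start[[g]] +
      frac * (config$age_share_end[[g]] - config$age_share_start[[g]])
    data.frame(year = years, age_group = g, population = round(total * share))
  })
  pop <- do.call(rbind, rows)
  all_rows <- stats::aggregate(population ~ year, pop, sum)
  all_rows$age_group <- "all"
  out <- rbind(pop, all_rows[, c("year", "age_group", "population")])
  out[order(out$year, match(out$age_group, c("all", AGE_GROUPS))), ]
}

#' Generate daily death counts and the generator truth
#'
#' Daily deaths per age group are Poisson (or negative-binomial when
#' `overdispersion > 1`) with mean
#' `population(d) * rate(d) / 1e5 * season(d) * (1 + g(T(d - lag)) / 100)`,
#' where `g` is the configured piecewise excess-mortality curve. The returned
#' truth object retains the injected curve and the noiseless expected deaths
#' for recovery testing.
#'
#' @param config a [generator_config()].
#' @param weather a `weather_field` from [generate_weather()] covering the
#'   configured dates.
#' @param population annual population table from [generate_population()].
#' @return list with `deaths` (data frame `date`, `age_group`, `deaths`,
#'   including the `all` sum) and `truth` (class `generator_truth`: config
#'   echo, seed, injected excess table `g`, expected noiseless deaths).
#' @export
generate_deaths <- function(config, weather, population) {
  stopifnot(inherits(config, "generator_config"))
  daily <- if (inherits(weather, "weather_field")) weather$daily else
    as_daily_series(weather)
  dates <- seq(config$start_date, config$end_date, by = "day")
  if (min(daily$date) > config$start_date || max(daily$date) < config$end_date) {
    stop(sprintf("weather does not cover configured dates: need %s..%s, have %s..%s",
                 format(config$start_date), format(config$end_date),
                 format(min(daily$date)), format(max(daily$date))), call. = FALSE)
  }
  temp <- daily$value[match(dates, daily$date)]
  k <- config$effect_lag_days
  temp_lagged <- if (k > 0L) c(rep(temp[1L], k), temp[seq_len(length(temp) - k)]) else temp
  pyears <- unique(population$year)
  need <- as.integer(format(c(config$start_date, config$end_date), "%Y"))
  if (min(pyears) > need[1] || max(pyears) < need[2]) {
    stop(sprintf("population table does not cover years %d..%d", need[1], need[2]),
         call. = FALSE)
  }
  doy <- day_of_year(dates)
  season <- 1 + config$seasonal_mortality_amplitude *
    cos(2 * pi * (doy - config$mortality_peak_doy) / 365.25)
  frac <- as.numeric(dates - config$start_date) /
    as.numeric(config$end_date - config$start_date)
  mu <- lapply(AGE_GROUPS, function(g) {
    pop <- interpolate_population(population, age_group = g, dates = dates)
    rate <- config$base_rate_start[[g]] +
      frac * (config$base_rate_end[[g]] - config$base_rate_start[[g]])
    gg <- excess_g(config, g, temp_lagged, dates)
    pmax(pop$value * rate / 1e5 * season * (1 + gg / 100), 0)
  })
  names(mu) <- AGE_GROUPS
  counts <- with_rng_seed(derive_seed(config$rng_seed, "deaths"), {
    lapply(AGE_GROUPS, function(g) {
      m <- mu[[g]]
      if (config$overdispersion > 1) {
        size <- m / (config$overdispersion - 1)
        stats::rnbinom(length(m), size = size, mu = m)
      } else {
        stats::rpois(length(m), m)
      }
    })
  })
  names(counts) <- AGE_GROUPS
  deaths <- do.call(rbind, c(
    list(data.frame(date = dates, age_group = "all",
                    deaths = Reduce(`+`, counts))),
    lapply(AGE_GROUPS, function(g)
      data.frame(date = dates, age_group = g, deaths = counts[[g]]))))
  tgrid <- seq(floor(min(temp)) - 2, ceiling(max(temp)) + 2, by = 0.5)
  gtab <- do.call(rbind, lapply(AGE_GROUPS, function(g) {
    do.call(rbind, lapply(seq_along(config$excess_curve_hot), function(i) {
      sp <- config$excess_curve_hot[[i]]
      ref_date <- sp$start %||% config$start_date
      data.frame(age_group = g, period = i,
                 period_start = format(ref_date),
                 temp = tgrid,
                 g = excess_g(config, g, tgrid, rep(ref_date, length(tgrid))))
    }))
  }))
  expected <- do.call(rbind, c(
    list(data.frame(date = dates, age_group = "all",
                    expected_deaths = Reduce(`+`, mu))),
    lapply(AGE_GROUPS, function(g)
      data.frame(date = dates, age_group = g, expected_deaths = mu[[g]]))))
  truth <- list(config = config, rng_seed = config$rng_seed,
                g_curve = gtab, expected_deaths = expected)
  class(truth) <- "generator_truth"
  list(deaths = deaths, truth = truth)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_weather()], [generate_population()]
#' and [generate_deaths()] under one configuration.
#'
#' @param config a [generator_config()].
#' @param subdaily passed to [generate_weather()].
#' @return list of class `synthetic_dataset` with `weather`, `population`,
#'   `deaths`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = generator_config(), subdaily = FALSE) {
  weather <- generate_weather(config, subdaily = subdaily)
  population <- generate_population(config)
  dd <- generate_deaths(config, weather, population)
  out <- list(weather = weather, population = population,
              deaths = dd$deaths, truth = dd$truth, config = config)
  class(out) <- "synthetic_dataset"
  out
}

#' Write a synthetic dataset to CSV/JSON files
#'
#' Writes `mortality.csv` (date, age_group, deaths), `population.csv` (year,
#' age_group, population), `weather.csv` (date\[, hour\], cell_id, value,
#' variable), `expected_deaths.csv`, and `truth.json` (config echo, seed, and
#' the injected excess curve).
#'
#' @param sim a `synthetic_dataset` from [simulate_dataset()].
#' @param outdir output directory, created if needed.
#' @return invisibly, the vector of file paths written.
#' @export
write_dataset <- function(sim, outdir) {
  stopifnot(inherits(sim, "synthetic_dataset"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- sim$weather$cells
  w$variable <- "tavg"
  if (!is.null(sim$weather$subdaily)) {
    s <- sim$weather$subdaily
    s$cell_id <- 0L
    s$variable <- "tavg"
    w$hour <- NA_integer_
    w <- rbind(w[, c("date", "hour", "cell_id", "value", "variable")],
               s[, c("date", "hour", "cell_id", "value", "variable")])
  }
  f <- file.path(outdir, "weather.csv")
  utils::write.csv(w, f, row.names = FALSE)
  paths <- c(paths, f)
  f <- file.path(outdir, "mortality.csv")
  utils::write.csv(sim$deaths, f, row.names = FALSE)
  paths <- c(paths, f)
  f <- file.path(outdir, "population.csv")
  utils::write.csv(sim$population, f, row.names = FALSE)
  paths <- c(paths, f)
  f <- file.path(outdir, "expected_deaths.csv")
  utils::write.csv(sim$truth$expected_deaths, f, row.names = FALSE)
  paths <- c(paths, f)
  cfg <- sim$config
  cfg$start_date <- format(cfg$start_date)
  cfg$end_date <- format(cfg$end_date)
  cfg$excess_curve_hot <- lapply(cfg$excess_curve_hot, function(sp) {
    sp$start <- if (!is.null(sp$start)) format(sp$start) else NULL
    sp$end <- if (!is.null(sp$end)) format(sp$end) else NULL
    sp$coef <- as.list(sp$coef)
    sp
  })
  if (!is.null(cfg$excess_curve_cold)) {
    cfg$excess_curve_cold$coef <- as.list(cfg$excess_curve_cold$coef)
  }
  class(cfg) <- NULL
  truth <- list(config = cfg, rng_seed = sim$truth$rng_seed,
                g_curve = sim$truth$g_curve)
  f <- file.path(outdir, "truth.json")
  jsonlite::write_json(truth, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, f)
  invisible(paths)
}
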