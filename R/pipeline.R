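PIPELINE_AGE_GROUPS <- c("all", "lt65", "65_74", "ge75", "ge65")

#' Pipeline configuration
#'
#' Assembles and validates the configuration of the end-to-end analysis:
#' either paths to mortality/population/weather CSVs or a `simulate` block (a
#' [generator_config()]), the baseline kernel, the window/lag designs, the
#' percentile levels, the sub-periods, the age groups, and the output
#' directory.
#'
#' @param mortality_csv,population_csv,weather_csv input file paths (ignored
#'   when `simulate` is given).
#' @param simulate optional [generator_config()]; when present the pipeline
#'   generates its inputs.
#' @param kernel_width,kernel_sigma baseline Gaussian filter settings (days).
#' @param windows list of `c(window, lag)` designs; default the primary 2-day
#'   1-day-lag design plus trailing 7- and 14-day windows.
#' @param levels percentile levels for [percentile_breaks()].
#' @param period_a,period_b sub-period date ranges for [subperiod_compare()].
#' @param age_groups subset of `all`, `lt65`, `65_74`, `ge75`, `ge65` (`ge65`
#'   is derived as the union of `65_74` and `ge75`).
#' @param outdir output directory (`NULL` for no file output).
#' @param seed seed overriding the simulate block's `rng_seed`.
#' @param fit_curves fit exposure-response curves (whole period + sub-periods).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mortality_csv = NULL, population_csv = NULL,
                            weather_csv = NULL, simulate = NULL,
                            kernel_width = 365, kernel_sigma = 365 / 12,
                            windows = list(c(2, 1), c(7, 0), c(14, 0)),
                            levels = DEFAULT_LEVELS,
                            period_a = c("1972-01-01", "1992-12-31"),
                            period_b = c("1994-01-01", "2014-12-31"),
                            age_groups = PIPELINE_AGE_GROUPS,
                            outdir = NULL, seed = NULL, fit_curves = TRUE) {
  if (is.null(simulate)) {
    for (f in c(mortality_csv, population_csv, weather_csv)) {
      if (is.null(f) || !file.exists(f)) {
        stop(sprintf("input file missing: %s (or provide a simulate block)",
                     f %||% "<NULL>"), call. = FALSE)
      }
    }
  } else {
    stopifnot(inherits(simulate, "generator_config"))
    if (!is.null(seed)) {
      simulate$rng_seed <- as.integer(seed)
    }
  }
  for (w in windows) {
    if (length(w) != 2L || w[1] < 1 || !w[2] %in% c(0, 1) ||
        (w[2] == 1 && w[1] < 2)) {
      stop("each window/lag entry must be c(window >= 1, lag in {0, 1})",
           call. = FALSE)
    }
  }
  age_groups <- match.arg(age_groups, PIPELINE_AGE_GROUPS, several.ok = TRUE)
  out <- list(mortality_csv = mortality_csv, population_csv = population_csv,
              weather_csv = weather_csv, simulate = simulate,
              kernel_width = kernel_width, kernel_sigma = kernel_sigma,
              windows = windows, levels = levels,
              period_a = as.Date(period_a), period_b = as.Date(period_b),
              age_groups = age_groups, outdir = outdir,
              seed = seed, fit_curves = fit_curves)
  class(out) <- "pipeline_config"
  out
}

#' Read a pipeline configuration from YAML or JSON
#'
#' File keys mirror the arguments of [pipeline_config()]; a `simulate` block
#' is passed to [generator_config()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @param ... overrides passed to [pipeline_config()].
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$simulate)) {
    sim <- raw$simulate
    for (f in c("age_share_start", "age_share_end", "base_rate_start",
                "base_rate_end")) {
      if (!is.null(sim[[f]])) sim[[f]] <- unlist(sim[[f]])
    }
    raw$simulate <- do.call(generator_config, sim)
  }
  if (!is.null(raw$windows)) {
    raw$windows <- lapply(raw$windows, function(w) as.numeric(unlist(w)))
  }
  args <- utils::modifyList(raw, list(...))
  do.call(pipeline_config, args)
}

#' Validate pipeline input tables
#'
#' Checks the mortality, population and weather tables for structural
#' problems: required columns, contiguous dates per age group, age-group
#' completeness, age-group death counts summing to the all-ages counts,
#' positive populations, plausible thermal-index ranges and missing weather
#' days. Problems are collected, never thrown; entries are marked `"error"`
#' or `"warning"`.
#'
#' @param mortality data frame `date`, `age_group`, `deaths`.
#' @param population data frame `year`, `age_group`, `population`.
#' @param weather data frame `date`, `value` (optionally `cell_id`).
#' @return data frame of class `validation_report` with columns `severity`,
#'   `check`, `message` (zero rows when clean).
#' @export
validate_inputs <- function(mortality = NULL, population = NULL,
                            weather = NULL) {
  issues <- list()
  add <- function(severity, check, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, check = check, message = message)
  }
  if (!is.null(mortality)) {
    if (!all(c("date", "age_group", "deaths") %in% names(mortality))) {
      add("error", "mortality_columns",
          "mortality table needs columns date, age_group, deaths")
    } else {
      mortality$date <- as.Date(mortality$date)
      for (g in unique(mortality$age_group)) {
        d <- sort(mortality$date[mortality$age_group == g])
        gaps <- which(diff(as.numeric(d)) != 1)
        if (length(gaps)) {
          add("error", "mortality_contiguity",
              sprintf("age group %s: %d date gap(s), first after %s",
                      g, length(gaps), format(d[gaps[1]])))
        }
      }
      if (any(mortality$deaths < 0, na.rm = TRUE)) {
        add("error", "mortality_negative", "negative death counts present")
      }
      groups <- unique(mortality$age_group)
      if (all(c("all", AGE_GROUPS) %in% groups)) {
        wide <- stats::reshape(
          mortality[mortality$age_group %in% c("all", AGE_GROUPS), ],
          idvar = "date", timevar = "age_group", direction = "wide")
        tot <- wide$deaths.lt65 + wide$deaths.65_74 + wide$deaths.ge75
        bad <- which(tot != wide$deaths.all)
        if (length(bad)) {
          add("error", "age_group_sum",
              sprintf("age-group deaths do not sum to all-ages on %d day(s), first %s",
                      length(bad), format(wide$date[bad[1]])))
        }
      } else if (length(setdiff(c("all", AGE_GROUPS), groups)) > 0 &&
                 "all" %in% groups && length(groups) > 1) {
        add("warning", "age_group_completeness",
            sprintf("age groups present: %s; cannot check the all-ages sum",
                    paste(groups, collapse = ", ")))
      }
    }
  }
  if (!is.null(population)) {
    if (!all(c("year", "age_group", "population") %in% names(population))) {
      add("error", "population_columns",
          "population table needs columns year, age_group, population")
    } else {
      if (any(population$population <= 0, na.rm = TRUE)) {
        add("error", "population_positive", "non-positive population values")
      }
      for (g in unique(population$age_group)) {
        if (sum(population$age_group == g) < 2L) {
          add("error", "population_years",
              sprintf("age group %s: fewer than 2 annual values", g))
        }
      }
    }
  }
  if (!is.null(weather)) {
    if (!all(c("date", "value") %in% names(weather))) {
      add("error", "weather_columns",
          "weather table needs columns date, value")
    } else {
      wd <- sort(unique(as.Date(weather$date)))
      gaps <- which(diff(as.numeric(wd)) != 1)
      if (length(gaps)) {
        missing_day <- wd[gaps[1]] + 1
        add("warning", "weather_contiguity",
            sprintf("%d missing weather day(s), first %s",
                    length(gaps), format(missing_day)))
      }
      v <- weather$value[is.finite(weather$value)]
      if (length(v) && (min(v) < -80 || max(v) > 60)) {
        add("warning", "weather_range",
            sprintf("thermal-index values outside plausible range -80..60 C (%.1f..%.1f)",
                    min(v), max(v)))
      }
    }
  }
  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(0), check = character(0),
               message = character(0))
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<validation_report> clean: no issues\n")
  } else {
    cat(sprintf("<validation_report> %d issue(s):\n", nrow(x)))
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  [%s] %s: %s\n", x$severity[i], x$check[i], x$message[i]))
    }
  }
  invisible(x)
}

# Add the derived >= 65 group (union of 65_74 and ge75) to long tables.
add_ge65 <- function(df, value_col) {
  if ("ge65" %in% df$age_group) return(df)
  sub <- df[df$age_group %in% c("65_74", "ge75"), , drop = FALSE]
  if (nrow(sub) == 0L) return(df)
  key <- if ("date" %in% names(df)) "date" else "year"
  agg <- stats::aggregate(sub[[value_col]], by = list(sub[[key]]), FUN = sum)
  names(agg) <- c(key, value_col)
  agg$age_group <- "ge65"
  rbind(df, agg[, names(df)])
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load, validation, baseline smoothing, relative
#' mortality, exposure pairing, percentile classification, category
#' statistics, sub-period comparison, trend estimation, and (optionally)
#' exposure-response curves; writes CSV tables, a markdown report and a run
#' log when `outdir` is set. Outputs are deterministic: identical
#' configuration and seed give byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `relative_mortality` (per age group),
#'   `pairs`, `breaks`, `tables` (one [category_table()] per design and age
#'   group), `trends`, `curves`, `validation`, and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$simulate)) {
    sim <- simulate_dataset(config$simulate)
    mortality <- sim$deaths
    population <- sim$population
    weather_cells <- sim$weather$cells
  } else {
    mortality <- utils::read.csv(config$mortality_csv)
    population <- utils::read.csv(config$population_csv)
    weather <- utils::read.csv(config$weather_csv)
    if ("hour" %in% names(weather)) {
      # Daily rows carry no hour; sub-daily rows are collapsed to daily means.
      daily_rows <- weather[is.na(weather$hour), , drop = FALSE]
      if (nrow(daily_rows) == 0L) {
        dm <- daily_mean_from_subdaily(weather[, c("date", "value")])
        daily_rows <- data.frame(date = dm$date, cell_id = 1L, value = dm$value)
      }
      weather <- daily_rows
    }
    if (!"cell_id" %in% names(weather)) weather$cell_id <- 1L
    weather_cells <- weather[, c("date", "cell_id", "value")]
  }
  mortality$date <- as.Date(mortality$date)
  weather_cells$date <- as.Date(weather_cells$date)
  report <- validate_inputs(mortality, population, weather_cells)
  if (any(report$severity == "error")) {
    stop(paste0("input validation failed:\n",
                paste(sprintf("  [%s] %s", report$check[report$severity == "error"],
                              report$message[report$severity == "error"]),
                      collapse = "\n")), call. = FALSE)
  }
  index <- spatial_average(weather_cells, index_kind = "tavg")
  kernel <- gaussian_kernel(config$kernel_width, config$kernel_sigma)

  mortality <- add_ge65(mortality, "deaths")
  population <- add_ge65(population, "population")

  relmort <- list()
  rate_trends <- list()
  for (g in config$age_groups) {
    dsub <- mortality[mortality$age_group == g, c("date", "deaths")]
    if (nrow(dsub) == 0L) stop(sprintf("no mortality rows for age group %s", g),
                               call. = FALSE)
    deaths <- daily_series(dsub$date, dsub$deaths, age_group = g)
    pop <- interpolate_population(population, age_group = g,
                                  dates = deaths$date)
    rate <- daily_rate(deaths, pop)
    expct <- expected_mortality(rate, kernel)
    rmres <- trim_to_full_years(relative_mortality(rate, expct))
    attr(rmres, "age_group") <- g
    relmort[[g]] <- rmres
    rate_trends[[g]] <- linear_trend(trim_to_full_years(rate))
  }

  study_range <- range(relmort[[1L]]$date)
  index_study <- index[index$date >= study_range[1] & index$date <= study_range[2], ]
  index_study <- thermal_index_series(index_study$date, index_study$value,
                                      index_kind = "tavg",
                                      provenance = "grid-average")
  breaks <- percentile_breaks(index_study, levels = config$levels)
  index_trend <- linear_trend(index_study)

  pairs_out <- list()
  tables <- list()
  for (w in config$windows) {
    for (g in config$age_groups) {
      key <- sprintf("w%d_l%d_%s", w[1], w[2], g)
      pr <- make_pairs(relmort[[g]], index_study, window_days = w[1],
                       lag_days = w[2])
      pairs_out[[key]] <- pr
      tables[[key]] <- category_table(pr, breaks, config$period_a,
                                      config$period_b)
    }
  }

  curves <- list()
  if (isTRUE(config$fit_curves)) {
    w1 <- config$windows[[1L]]
    for (g in config$age_groups) {
      pr <- pairs_out[[sprintf("w%d_l%d_%s", w1[1], w1[2], g)]]
      periods <- list(
        whole = c(study_range[1], study_range[2]),
        period_a = config$period_a,
        period_b = config$period_b)
      for (pn in names(periods)) {
        sel <- pr[pr$date >= periods[[pn]][1] & pr$date <= periods[[pn]][2], ]
        if (nrow(sel) >= 20L) {
          curves[[paste0(g, "_", pn)]] <- fit_curve(sel, period = pn)
        }
      }
    }
  }

  rm_trends <- lapply(relmort, linear_trend)
  trend_tab <- do.call(rbind, c(
    lapply(names(rate_trends), function(g)
      data.frame(series = "mortality_rate", age_group = g,
                 slope_per_decade = rate_trends[[g]]$slope,
                 ci_low = rate_trends[[g]]$ci_low,
                 ci_high = rate_trends[[g]]$ci_high,
                 p_value = rate_trends[[g]]$p_value)),
    lapply(names(rm_trends), function(g)
      data.frame(series = "relative_mortality", age_group = g,
                 slope_per_decade = rm_trends[[g]]$slope,
                 ci_low = rm_trends[[g]]$ci_low,
                 ci_high = rm_trends[[g]]$ci_high,
                 p_value = rm_trends[[g]]$p_value)),
    list(data.frame(series = "thermal_index", age_group = NA,
                    slope_per_decade = index_trend$slope,
                    ci_low = index_trend$ci_low, ci_high = index_trend$ci_high,
                    p_value = index_trend$p_value))))

  files <- character(0)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    wpath <- function(name) file.path(config$outdir, name)
    rm_df <- do.call(rbind, lapply(names(relmort), function(g)
      data.frame(date = relmort[[g]]$date, age_group = g,
                 relative_mortality = relmort[[g]]$value)))
    utils::write.csv(rm_df, wpath("relative_mortality.csv"), row.names = FALSE)
    files <- c(files, wpath("relative_mortality.csv"))
    pairs_df <- do.call(rbind, lapply(pairs_out, function(p)
      data.frame(date = p$date, age_group = p$age_group, window = p$window,
                 lag = p$lag, exposure = p$exposure, response = p$response)))
    utils::write.csv(pairs_df, wpath("pairs.csv"), row.names = FALSE)
    files <- c(files, wpath("pairs.csv"))
    cat_df <- do.call(rbind, lapply(names(tables), function(k) {
      tt <- as.data.frame(tables[[k]])
      tt$design <- k
      tt
    }))
    utils::write.csv(cat_df, wpath("category_tables.csv"), row.names = FALSE)
    files <- c(files, wpath("category_tables.csv"))
    utils::write.csv(trend_tab, wpath("trends.csv"), row.names = FALSE)
    files <- c(files, wpath("trends.csv"))
    if (length(curves)) {
      curve_df <- do.call(rbind, lapply(names(curves), function(k) {
        cv <- as.data.frame(curves[[k]])
        cv$curve <- k
        cv
      }))
      utils::write.csv(curve_df, wpath("curves.csv"), row.names = FALSE)
      files <- c(files, wpath("curves.csv"))
    }
    w1 <- config$windows[[1L]]
    primary <- tables[grepl(sprintf("^w%d_l%d_", w1[1], w1[2]), names(tables))]
    report_lines <- c(
      "# Relative mortality by thermal-index percentile category", "",
      sprintf("Study period: %s .. %s", format(study_range[1]),
              format(study_range[2])),
      sprintf("Primary design: %d-day response window, %d-day lag",
              w1[1], w1[2]),
      sprintf("Sub-periods: %s..%s and %s..%s",
              format(config$period_a[1]), format(config$period_a[2]),
              format(config$period_b[1]), format(config$period_b[2])), "",
      format_category_report(primary))
    writeLines(report_lines, wpath("report.md"))
    files <- c(files, wpath("report.md"))
    log <- list(
      kernel_width = config$kernel_width, kernel_sigma = config$kernel_sigma,
      windows = config$windows, levels = config$levels,
      period_a = format(config$period_a), period_b = format(config$period_b),
      age_groups = config$age_groups,
      seed = if (!is.null(config$simulate)) config$simulate$rng_seed else config$seed,
      simulated = !is.null(config$simulate),
      n_categories = length(config$levels) + 1L,
      validation_issues = nrow(report))
    jsonlite::write_json(log, wpath("run_log.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- c(files, wpath("run_log.json"))
  }

  invisible(list(relative_mortality = relmort, pairs = pairs_out,
                 breaks = breaks, tables = tables, trends = trend_tab,
                 curves = curves, validation = report, files = files,
                 truth = if (!is.null(config$simulate)) sim$truth else NULL))
}
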