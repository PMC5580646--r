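# relmort

Biometeorological analysis of mortality and thermal extremes in R: stationary
**relative mortality** via Gaussian baseline smoothing, **percentile-category**
excess-mortality statistics, **sub-period sensitivity comparisons**, and smooth
**exposure-response curves** — plus a synthetic-data generator with retained
ground truth so the whole pipeline is testable without access to confidential
mortality registers.

## The problem and the method

Daily death counts mix a declining long-term trend, a winter-peaking seasonal
cycle, and the short-lived excursions caused by heat waves and cold spells.
To quantify the weather-driven excursions across decades — and to ask whether
a population's sensitivity to heat has changed — the slow components are
removed by the Koppe–Jendritzky construction:

- daily mortality rate: `r(d) = deaths(d) / population(d) × 1e5`, population
  interpolated daily from annual values;
- expected mortality `E(d)`: centered Gaussian moving average of `r` with a
  365-day window (`w_j ∝ exp(−j²/2σ²)`, Σw = 1, default σ = 365/12 days),
  which keeps the seasonal cycle but smooths day-to-day variability; the
  filter shortens the series by 182 days at each end, and the analysis keeps
  full calendar years;
- relative mortality: `RM(d) = 100 · (r(d) − E(d)) / E(d)`, stationary
  (trend- and season-free) by construction.

`RM` is then paired with a thermal index — daily mean air temperature or a
precomputed physiologically equivalent temperature (PET) — under the primary
design (index on day *d* vs mean of `RM(d)`, `RM(d+1)`; a one-day lag) or
trailing 7-/14-day windows. The index distribution is cut at the 1, 2.5, 5,
10, 25, 50, 75, 90, 95, 97.5, 99% percentiles of the whole study period into
12 categories, and per category and age group the package reports the mean
`RM` with 95% CI, its linear time trend (%/decade), sub-period means
(1972–1992 vs 1994–2014 by default) with a Welch two-sample t-test and
Shapiro–Wilk checks. Smooth exposure-response curves with pointwise 95% bands
come from penalized thin-plate regression splines (GAM, GCV or REML).

Intended users: environmental epidemiologists and biometeorologists studying
temperature-mortality relationships, and anyone needing a tested reference
implementation of the relative-mortality baseline.

## Worked example

Simulate a 45-year study (defaults emulate a northern-European hospital
district: population 1.0→1.6 M, crude mortality ≈2.2 per 100,000/day and
declining, winter-peaking seasonality, warming AR(1) weather, J-shaped heat
excess), then run the analysis:

```r
library(relmort)

cfg <- generator_config(rng_seed = 42)
sim <- simulate_dataset(cfg)

d    <- sim$deaths[sim$deaths$age_group == "all", ]
pop  <- interpolate_population(sim$population, "all", dates = as.Date(d$date))
rate <- daily_rate(daily_series(d$date, d$deaths, age_group = "all"), pop)
rmx  <- trim_to_full_years(relative_mortality(rate, expected_mortality(rate)))

linear_trend(trim_to_full_years(rate))
#> trend -0.1095 per decade (95% CI -0.1149, -0.1042), p = 0, n = 16436
linear_trend(rmx)
#> trend -0.006002 per decade (95% CI -0.2376, 0.2256), p = 0.959, n = 15706
```

The raw rate falls about −0.11 per 100,000 per decade; relative mortality has
no trend left. Pair it with temperature and summarize by percentile category:

```r
index  <- thermal_index_series(sim$weather$daily$date, sim$weather$daily$value)
pairs  <- make_pairs(rmx, index, window_days = 2, lag_days = 1)
breaks <- percentile_breaks(pairs$exposure)
tab    <- category_table(pairs, breaks)
tab[c(1, 6, 11, 12), c("percentiles", "n", "mean", "ci_low", "ci_high")]
#>    percentiles    n   mean ci_low ci_high
#> 1          0-1  158  3.007  0.833   5.181
#> 6        25-50 3926  0.192 -0.207   0.591
#> 11     97.5-99  235 10.112  8.408  11.817
#> 12      99-100  158 16.804 14.458  19.151
```

Relative mortality is flat in the mid-range, mildly elevated in the coldest
1% and strongly elevated (≈ +17%, CI 14.5–19.2) above the 99th percentile —
the injected J-shape, recovered. The smooth exposure-response curve shows the
same:

```r
curve <- fit_curve(pairs)
evaluate_curve(curve, c(-20, 0, 20, 24))
#>     x   fit band_low band_high
#> 1 -20 4.234   1.0639     7.404
#> 2   0 0.437  -0.0448     0.919
#> 3  20 0.463  -0.0909     1.017
#> 4  24 8.779   7.9552     9.603
```

`run_pipeline(pipeline_config(simulate = cfg, outdir = "out"))` runs every
stage (validation, baseline, pairing, categories, trends, sub-period tests,
curves) and writes CSV tables, a markdown report and a run log; rerunning
with the same config and seed reproduces the outputs byte for byte. A thin
CLI over the same functions ships in `inst/cli/relmort-cli.R`
(`simulate`, `baseline`, `pairs`, `categories`, `curves`, `trends`, `run`).

Real data enter through the same CSV contracts: `mortality.csv`
(`date, age_group ∈ {all, lt65, 65_74, ge75}, deaths`), `population.csv`
(`year, age_group, population`), `weather.csv`
(`date[, hour], cell_id, value, variable`).

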