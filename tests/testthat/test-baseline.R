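test_that("population interpolation is linear between mid-year anchors", {
  pop <- data.frame(year = c(2000, 2001), population = c(100, 200))
  ds <- interpolate_population(pop)
  # halfway between the two anchors (182nd day of 2000 + half the gap)
  a1 <- as.Date("2000-01-01") + 181
  a2 <- as.Date("2001-01-01") + 181
  mid <- a1 + as.numeric(a2 - a1) / 2
  expect_equal(ds$value[ds$date == mid], 150)
  # endpoints held flat outside the anchors
  expect_equal(ds$value[1], 100)
  expect_equal(ds$value[nrow(ds)], 200)
})

test_that("constant annual population gives a constant daily series", {
  pop <- data.frame(year = 2000:2004, population = rep(1234, 5))
  expect_equal(unique(interpolate_population(pop)$value), 1234)
})

test_that("increasing annual population gives a monotone daily series", {
  pop <- data.frame(year = 2000:2002, population = c(1.0e6, 1.2e6, 1.4e6))
  ds <- interpolate_population(pop)
  expect_true(all(diff(ds$value) >= 0))
})

test_that("a single annual value cannot be interpolated", {
  expect_error(interpolate_population(data.frame(year = 2000, population = 10)),
               "two annual")
})

test_that("daily rate is deaths per 100,000", {
  deaths <- toy_series(c(22, 0, 11))
  pop <- toy_series(rep(1e6, 3))
  r <- daily_rate(deaths, pop)
  expect_equal(r$value, c(2.2, 0, 1.1))
  expect_error(daily_rate(deaths, toy_series(c(1e6, 0, 1e6))), "positive")
})

test_that("kernel weights are symmetric, positive, normalized and peaked", {
  k <- gaussian_kernel(365, 365 / 12)
  expect_equal(sum(k$weights), 1, tolerance = 1e-12)
  expect_true(all(k$weights > 0))
  expect_equal(k$weights, rev(k$weights))
  expect_true(all(diff(k$weights[1:(k$half_width + 1)]) > 0))
  # sigma -> Inf limit: uniform weights
  expect_equal(gaussian_kernel(3, 1e9)$weights, rep(1 / 3, 3), tolerance = 1e-9)
  expect_error(gaussian_kernel(4), "odd")
  expect_error(gaussian_kernel(365, -1), "sigma")
})

test_that("smoothing reproduces constants and linear ramps in the interior", {
  k <- gaussian_kernel(31, 5)
  const <- toy_series(rep(4.2, 200))
  sm <- expected_mortality(const, k)
  expect_equal(unique(round(sm$value, 12)), 4.2)
  expect_equal(nrow(sm), 200 - 2 * k$half_width)
  ramp <- toy_series(seq(0, 10, length.out = 200))
  smr <- expected_mortality(ramp, k)
  expect_equal(smr$value, ramp$value[(k$half_width + 1):(200 - k$half_width)],
               tolerance = 1e-12)
})

test_that("smoothing matches the brute-force convolution oracle", {
  set.seed(5)
  x <- rnorm(400)
  k <- gaussian_kernel(61, 10)
  sm <- expected_mortality(toy_series(x), k)
  expect_equal(sm$value, naive_convolve(x, k$weights), tolerance = 1e-12)
})

test_that("white-noise variance is reduced by the filter's sum of squared weights", {
  set.seed(11)
  s <- 2.5
  x <- rnorm(10000, sd = s)
  k <- gaussian_kernel(91, 15)
  sm <- expected_mortality(toy_series(x), k)
  target <- s * sqrt(sum(k$weights^2))
  expect_lt(abs(sd(sm$value) - target) / target, 0.1)
  expect_lt(var(sm$value), var(x) / 10)
})

test_that("an annual sinusoid is attenuated by the kernel gain with unchanged phase", {
  n <- 3000
  t <- seq_len(n)
  x <- sin(2 * pi * t / 365.25)
  k <- gaussian_kernel(365, 365 / 12)
  sm <- expected_mortality(toy_series(x), k)
  oracle <- naive_convolve(x, k$weights)
  expect_equal(sm$value, oracle, tolerance = 1e-12)
  # empirical gain ~ exp(-(2 pi sigma / P)^2 / 2), phase preserved
  inner <- t[(k$half_width + 1):(n - k$half_width)]
  gain <- sum(sm$value * x[inner]) / sum(x[inner]^2)
  expect_equal(gain, exp(-(2 * pi * (365 / 12) / 365.25)^2 / 2),
               tolerance = 1e-3)
})

test_that("filter is linear in its input", {
  set.seed(2)
  x <- rnorm(300); y <- rnorm(300)
  k <- gaussian_kernel(31, 6)
  lhs <- expected_mortality(toy_series(2 * x + 3 * y), k)$value
  rhs <- 2 * expected_mortality(toy_series(x), k)$value +
    3 * expected_mortality(toy_series(y), k)$value
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("second smoothing pass changes a white-noise series less than the first", {
  set.seed(3)
  x <- toy_series(rnorm(1200))
  k <- gaussian_kernel(61, 10)
  s1 <- expected_mortality(x, k)
  s2 <- expected_mortality(s1, k)
  d1 <- sqrt(mean((s1$value - x$value[(k$half_width + 1):(1200 - k$half_width)])^2))
  inner <- (k$half_width + 1):(nrow(s1) - k$half_width)
  d2 <- sqrt(mean((s2$value - s1$value[inner])^2))
  expect_lt(d2, d1)
})

test_that("relative mortality is the percent deviation from expected", {
  obs <- toy_series(c(12, 10, 8))
  expct <- toy_series(c(10, 10, 10))
  expect_equal(relative_mortality(obs, expct)$value, c(20, 0, -20))
  expect_equal(relative_mortality(expct, expct)$value, rep(0, 3))
  expect_error(relative_mortality(obs, toy_series(c(1, 0, 1))), "positive")
})

test_that("series shorter than the kernel is refused", {
  expect_error(expected_mortality(toy_series(rnorm(100)), gaussian_kernel(365)),
               "exceed kernel width")
})

test_that("trimming keeps exactly the fully covered calendar years", {
  d <- seq(as.Date("1971-07-02"), as.Date("2015-06-30"), by = "day")
  tr <- trim_to_full_years(daily_series(d, seq_along(d)))
  expect_equal(min(tr$date), as.Date("1972-01-01"))
  expect_equal(max(tr$date), as.Date("2014-12-31"))

  one <- seq(as.Date("2003-01-01"), as.Date("2003-12-31"), by = "day")
  expect_equal(nrow(trim_to_full_years(daily_series(one, seq_along(one)))), 365L)

  d2 <- seq(as.Date("2000-01-02"), as.Date("2001-12-31"), by = "day")
  tr2 <- trim_to_full_years(daily_series(d2, seq_along(d2)))
  expect_equal(format(range(tr2$date), "%Y"), c("2001", "2001"))

  d3 <- seq(as.Date("2000-02-01"), as.Date("2000-11-30"), by = "day")
  expect_error(trim_to_full_years(daily_series(d3, seq_along(d3))),
               "complete calendar year")
})

test_that("linear trend recovers an exact slope per decade and handles constants", {
  d <- seq(as.Date("1972-01-01"), length.out = 8000, by = "day")
  dec <- as.numeric(d - d[1]) / 3652.5
  tr <- linear_trend(daily_series(d, 5 + 0.44 * dec))
  expect_equal(tr$slope, 0.44, tolerance = 1e-10)
  expect_lt(tr$ci_high - tr$ci_low, 1e-8)
  expect_lt(tr$p_value, 1e-10)

  trc <- linear_trend(daily_series(d, rep(3.3, length(d))))
  expect_equal(trc$slope, 0)
  expect_equal(trc$p_value, 1)
})

test_that("declining synthetic rate trend is recovered across seeds", {
  # target crude trend: rates scaled so the all-age rate falls -0.116/decade
  slopes <- vapply(1:25, function(s) {
    cfg <- small_config(
      seed = s, start_date = as.Date("1995-01-01"),
      end_date = as.Date("2009-12-31"),
      base_rate_start = c(lt65 = 2, "65_74" = 8, ge75 = 30),
      base_rate_end = c(lt65 = 2, "65_74" = 8, ge75 = 30) * (1 - 0.0279 * 1.5),
      seasonal_mortality_amplitude = 0)
    sim <- simulate_dataset(cfg)
    deaths <- sim$deaths[sim$deaths$age_group == "all", ]
    pop <- interpolate_population(sim$population, "all",
                                  dates = as.Date(deaths$date))
    linear_trend(daily_rate(daily_series(deaths$date, deaths$deaths), pop))$slope
  }, numeric(1))
  # crude rate 0.8*2 + 0.1*8 + 0.1*30 = 5.4, falling linearly by a fraction
  # 0.0279 * 1.5 over 1.5 decades -> slope = -5.4 * 0.0279 per decade
  expected <- -5.4 * 0.0279
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - expected), 3 * mc_se)
})

test_that("relative mortality of trend-free synthetic data is centered on zero", {
  cfg <- small_config(seed = 21L, seasonal_mortality_amplitude = 0)
  sim <- simulate_dataset(cfg)
  deaths <- sim$deaths[sim$deaths$age_group == "all", ]
  pop <- interpolate_population(sim$population, "all",
                                dates = as.Date(deaths$date))
  rate <- daily_rate(daily_series(deaths$date, deaths$deaths), pop)
  rm_series <- relative_mortality(rate, expected_mortality(rate))
  expect_lt(abs(mean(rm_series$value)), 1)
  tr <- linear_trend(rm_series)
  expect_true(tr$ci_low < 0 && tr$ci_high > 0)
})
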