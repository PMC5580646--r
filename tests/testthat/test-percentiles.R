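test_that("quantile breakpoints follow linear interpolation of order statistics", {
  br <- percentile_breaks(as.numeric(1:100), levels = c(0.25, 0.5, 0.75))
  expect_equal(br$breakpoints, unname(quantile(1:100, c(.25, .5, .75), type = 7)))
  expect_equal(br$breakpoints[2], 50.5)
})

test_that("the 11 default levels define exactly 12 categories tiling the range", {
  set.seed(1)
  x <- rnorm(5000)
  br <- percentile_breaks(x)
  expect_equal(length(br$levels), 11L)
  expect_equal(length(br$breakpoints), 11L)
  cats <- classify_index(x, br)
  expect_equal(sort(unique(cats)), 1:12)
  rng <- relmort:::category_ranges(br)
  expect_equal(rng$range_low[1], min(x))
  expect_equal(rng$range_high[12], max(x))
  expect_equal(rng$range_low[-1], rng$range_high[-12])
})

test_that("breaks are monotone in level and invariant under permutation", {
  set.seed(2)
  x <- rnorm(1000)
  br1 <- percentile_breaks(x)
  br2 <- percentile_breaks(sample(x))
  expect_identical(br1$breakpoints, br2$breakpoints)
  expect_true(all(diff(br1$breakpoints) >= 0))
})

test_that("a constant series yields degenerate categories with a warning", {
  expect_warning(br <- percentile_breaks(rep(3, 100)), "degenerate")
  expect_true(all(br$breakpoints == 3))
  expect_true(br$degenerate)
})

test_that("classification is right-closed with ties going to the lower category", {
  set.seed(3)
  x <- rnorm(2000)
  br <- percentile_breaks(x)
  # value exactly at the first breakpoint stays in category 1
  expect_equal(classify_index(br$breakpoints[1], br), 1L)
  expect_equal(classify_index(br$breakpoints[11], br), 11L)
  # values beyond the observed range are still classified
  expect_equal(classify_index(br$data_min - 10, br), 1L)
  expect_equal(classify_index(br$data_max + 10, br), 12L)
  expect_error(classify_index(NaN, br), "non-finite")
  # brute-force linear-scan oracle
  oracle <- function(v) {
    k <- 1L
    for (b in br$breakpoints) if (v > b) k <- k + 1L
    k
  }
  v <- c(rnorm(500), br$breakpoints)
  expect_equal(classify_index(v, br), vapply(v, oracle, integer(1)))
})

make_test_pairs <- function(dates, exposure, response, age_group = "all") {
  out <- data.frame(date = as.Date(dates), exposure = exposure,
                    response = response, window = 1L, lag = 0L,
                    age_group = age_group)
  class(out) <- c("exposure_pairs", "data.frame")
  out
}

test_that("category means and t-intervals are computed per category", {
  set.seed(4)
  x <- rnorm(600)
  br <- percentile_breaks(x)
  d <- seq(as.Date("2000-01-01"), by = "day", length.out = 600)
  p <- make_test_pairs(d, x, rep(c(0, 10, 20), 200))
  cs <- category_summary(p, br)
  expect_equal(nrow(cs), 12L)
  expect_equal(sum(cs$n), 600L)
  k <- classify_index(x, br)
  expect_equal(cs$mean[5], mean(p$response[k == 5]))
  expect_true(all(cs$ci_low <= cs$mean & cs$mean <= cs$ci_high, na.rm = TRUE))
  # all responses equal -> zero-width intervals
  p2 <- make_test_pairs(d, x, rep(7, 600))
  cs2 <- category_summary(p2, br)
  expect_true(all(cs2$mean == 7))
  expect_true(all(abs(cs2$ci_high - cs2$ci_low) < 1e-12))
})

test_that("pooled category means equal the n-weighted combination of sub-period means", {
  set.seed(5)
  n <- 800
  d <- seq(as.Date("1990-01-01"), by = "day", length.out = n)
  x <- rnorm(n)
  p <- make_test_pairs(d, x, rnorm(n))
  br <- percentile_breaks(x)
  cs <- category_summary(p, br)
  half <- d[n %/% 2]
  sp <- subperiod_compare(p, br, period_a = c(d[1], half),
                          period_b = c(half + 1, d[n]))
  pooled <- (sp$n_a * sp$mean_a + sp$n_b * sp$mean_b) / (sp$n_a + sp$n_b)
  expect_equal(pooled[cs$n > 0], cs$mean[cs$n > 0], tolerance = 1e-12)
  expect_equal(sp$n_a + sp$n_b, cs$n)
})

test_that("category trends recover an exact linear drift and flag tiny categories", {
  n <- 1200
  d <- seq(as.Date("1980-01-01"), by = "day", length.out = n)
  dec <- as.numeric(d - d[1]) / 3652.5
  x <- rep(seq(-2, 2, length.out = 40), 30)
  p <- make_test_pairs(d, x, 1 - 3.9 * dec)
  br <- percentile_breaks(x, levels = c(0.1, 0.25, 0.5, 0.75, 0.9))
  ct <- category_trend(p, br)
  defined <- ct$defined
  expect_true(all(abs(ct$trend[defined] - (-3.9)) < 1e-8))
  expect_true(all(ct$stars[defined] == "***"))
  # constant responses: zero slope
  ct0 <- category_trend(make_test_pairs(d, x, rep(2, n)), br)
  expect_true(all(abs(ct0$trend[ct0$defined]) < 1e-12))
})

test_that("time-shuffled responses rarely show a significant category trend", {
  set.seed(6)
  n <- 730
  d <- seq(as.Date("2000-01-01"), by = "day", length.out = n)
  x <- rnorm(n)
  y <- rnorm(n)
  br <- percentile_breaks(x, levels = c(0.25, 0.5, 0.75))
  covered <- vapply(1:100, function(i) {
    p <- make_test_pairs(d, x, sample(y))
    ct <- category_trend(p, br)
    all(ct$ci_low[ct$defined] < 0 & ct$ci_high[ct$defined] > 0)
  }, logical(1))
  # 4 categories jointly covering zero at 95% each
  expect_gte(mean(covered), 0.70)
})

test_that("Welch comparison: identical samples give t = 0, p = 1", {
  y <- c(1, 2, 3, 4, 5)
  d_a <- seq(as.Date("2000-01-01"), by = "day", length.out = 5)
  d_b <- seq(as.Date("2001-01-01"), by = "day", length.out = 5)
  p <- make_test_pairs(c(d_a, d_b), rep(0, 10), c(y, y))
  br <- suppressWarnings(percentile_breaks(rep(0, 10), levels = c(0.5)))
  sp <- subperiod_compare(p, br, period_a = c(d_a[1], d_a[5]),
                          period_b = c(d_b[1], d_b[5]))
  row <- sp[sp$n_a > 0, ][1, ]
  expect_equal(row$welch_t, 0)
  expect_equal(row$welch_p, 1)
})

test_that("Welch t equals the pooled t under equal variances and sizes", {
  set.seed(7)
  ya <- rnorm(40)
  yb <- ya + 0.5  # same variance exactly
  tw <- t.test(ya, yb, var.equal = FALSE)
  tp <- t.test(ya, yb, var.equal = TRUE)
  expect_equal(unname(tw$statistic), unname(tp$statistic), tolerance = 1e-12)
  expect_equal(unname(tw$parameter), unname(tp$parameter), tolerance = 1e-9)
})

test_that("sub-period comparison flags categories with too few points", {
  d <- seq(as.Date("2000-01-01"), by = "day", length.out = 40)
  x <- c(rep(-1, 39), 5)  # one lonely hot day
  set.seed(8)
  p <- make_test_pairs(d, x, rnorm(40))
  br <- suppressWarnings(percentile_breaks(x, levels = c(0.5, 0.9)))
  sp <- subperiod_compare(p, br, period_a = c(d[1], d[20]),
                          period_b = c(d[21], d[40]))
  expect_false(sp$defined[3])
  expect_true(is.na(sp$welch_p[3]))
})

test_that("shapiro p-values are reported and large samples are thinned, not refused", {
  set.seed(9)
  n <- 22000
  d <- seq(as.Date("1960-01-01"), by = "day", length.out = n)
  p <- make_test_pairs(d, rnorm(n), rnorm(n))
  br <- percentile_breaks(p$exposure, levels = c(0.5))
  sp <- subperiod_compare(p, br, period_a = c(d[1], d[n %/% 2]),
                          period_b = c(d[n %/% 2 + 1], d[n]))
  expect_true(all(is.finite(sp$shapiro_p_a)))
  expect_true(all(is.finite(sp$shapiro_p_b)))
})

test_that("category table assembles the summary, trend and sub-period columns", {
  set.seed(10)
  n <- 900
  d <- seq(as.Date("1972-01-01"), by = "day", length.out = n)
  p <- make_test_pairs(d, rnorm(n), rnorm(n))
  br <- percentile_breaks(p$exposure)
  tb <- category_table(p, br, period_a = c(d[1], d[450]),
                       period_b = c(d[451], d[900]))
  expect_s3_class(tb, "category_table")
  expect_equal(nrow(tb), 12L)
  expect_true(all(c("percentiles", "mean", "trend", "mean_a", "mean_b",
                    "welch_p", "shapiro_p_a") %in% names(tb)))
  rep_lines <- format_category_report(tb)
  expect_true(any(grepl("99-100", rep_lines)))
  expect_true(any(grepl("multiple-testing", rep_lines)))
})
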