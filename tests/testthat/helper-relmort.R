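# Shared fixtures and oracles, built in code.

# A fast, small generator configuration: 7 years, flat population structure,
# modest counts. Effects off unless a test injects them.
small_config <- function(seed = 1L, ...) {
  defaults <- list(
    start_date = as.Date("2000-01-01"), end_date = as.Date("2006-12-31"),
    population_start = 5e5, population_end = 5e5,
    age_share_start = c(lt65 = 0.8, "65_74" = 0.1, ge75 = 0.1),
    age_share_end = c(lt65 = 0.8, "65_74" = 0.1, ge75 = 0.1),
    base_rate_start = c(lt65 = 2, "65_74" = 8, ge75 = 30),
    base_rate_end = c(lt65 = 2, "65_74" = 8, ge75 = 30),
    seasonal_mortality_amplitude = 0.1,
    excess_curve_hot = NULL_hot(),
    excess_curve_cold = NULL,
    rng_seed = seed)
  overrides <- list(...)
  args <- defaults
  args[names(overrides)] <- overrides
  do.call(generator_config, args)
}

# Zero-effect hot arm (threshold far above any generated temperature).
NULL_hot <- function() list(list(threshold = 1e6, slope = 0))

# Brute-force O(n*w) centered-convolution oracle; drops half-width edges.
naive_convolve <- function(x, weights) {
  hw <- (length(weights) - 1) / 2
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in (hw + 1):(n - hw)) {
    out[i] <- sum(weights * x[(i - hw):(i + hw)])
  }
  out[(hw + 1):(n - hw)]
}

# Deterministic short daily series for arithmetic checks.
toy_series <- function(values, start = "2000-01-01", ...) {
  daily_series(seq(as.Date(start), by = "day", length.out = length(values)),
               values, ...)
}
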