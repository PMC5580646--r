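Package: relmort
Title: Relative Mortality and Thermal Extremes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for biometeorological mortality analysis: stationary
    relative-mortality series via 365-day Gaussian baseline smoothing of daily
    mortality rates, percentile-category summaries of excess mortality against
    thermal indices (air temperature or physiologically equivalent
    temperature), category-wise time trends, sub-period comparisons with Welch
    t-tests, and smooth exposure-response curves from penalized regression
    splines. Includes a synthetic-data generator that emulates multi-decade
    daily death counts, population growth and weather with configurable
    heat- and cold-excess curves, retaining the injected ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
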