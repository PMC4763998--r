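Package: washfrontier
Title: Frontier-Normalized Rates of Change in Water and Sanitation Coverage
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures national progress towards universal access to improved
    drinking water and sanitation on a scale that is comparable across
    countries with different starting points. Absolute rates of change in
    coverage are estimated by ordinary least squares from household-survey
    time series, a best-performer frontier curve (constrained to zero rate
    at 100% coverage) gives the maximum achievable rate at every coverage
    level, and each country's rate is normalized by that maximum to fall in
    [-1, 1]. Includes frontier-point identification (upper convex hull,
    Pareto dominance or an explicit list), one-sided Grubbs outlier
    screening, principal-component and stepwise regression tools for
    relating progress to socioeconomic indicators (linear and fractional-
    logit models), a synthetic-data generator for end-to-end validation,
    and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
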