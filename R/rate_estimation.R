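# Absolute rates of change: OLS slope of coverage on calendar year.

#' Estimate a country's absolute rate of change in coverage
#'
#' Fits coverage (percent) on calendar year by ordinary least squares,
#' using every observation including duplicate years. The slope is the
#' absolute rate of change in percentage points per year. The fit is taken
#' at face value: fitted coverage is not truncated to \[0, 100\] over the
#' observation window, and no weighting by survey size is applied.
#'
#' When the response has zero variance (all surveys report the same
#' coverage) the coefficient of determination is defined as 0 rather than
#' left undefined, so downstream reporting stays total.
#'
#' @param series a [coverage_series()] that passes the inclusion filter
#'   (checked; see [apply_inclusion_filter()]).
#' @param require_inclusion enforce the 5-point / 3-year filter
#'   (default `TRUE`).
#' @return Object of class `rate_estimate`: list with `country`, `service`,
#'   `slope` (%/year), `slope_se`, `intercept` (coverage at year 0 of the
#'   centred scale, i.e. calendar year 2000), `r_squared`, `n_points`,
#'   `first_year`, `last_year`.
#' @examples
#' s <- coverage_series("KEN", "water", 2000:2004, c(50, 51, 52, 53, 54))
#' estimate_rate(s)$slope
#' @export
estimate_rate <- function(series, require_inclusion = TRUE) {
  stopifnot(inherits(series, "coverage_series"))
  if (require_inclusion) {
    dec <- apply_inclusion_filter(series)
    if (!dec$included)
      stop_wf("series %s/%s fails the inclusion filter: %s",
              dec$country, dec$service, dec$reason,
              class = "wf_inclusion_error")
  }
  if (length(unique(series$year)) < 2L)
    stop_wf("all observations fall in a single year; the trend is undefined",
            class = "wf_degenerate_design_error")
  # centre at 2000 so the intercept is the fitted year-2000 coverage
  t <- series$year - 2000L
  fit <- lm(coverage ~ t, data = data.frame(t = t, coverage = series$coverage))
  cf <- coef(fit)
  # diagnostics computed directly (rather than via summary.lm, which warns
  # on the exact fits that arise in noiseless validation worlds)
  rss <- sum(residuals(fit)^2)
  tss <- sum((series$coverage - mean(series$coverage))^2)
  r2 <- if (tss == 0) 0 else 1 - rss / tss
  sxx <- sum((t - mean(t))^2)
  se <- sqrt(rss / (nrow(series) - 2L) / sxx)
  structure(list(country = attr(series, "country"),
                 service = attr(series, "service"),
                 slope = unname(cf["t"]),
                 slope_se = se,
                 intercept = unname(cf["(Intercept)"]),
                 r_squared = r2,
                 n_points = nrow(series),
                 first_year = min(series$year),
                 last_year = max(series$year)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Rate of change, %s/%s (%d points, %d-%d):\n",
              x$country, x$service, x$n_points, x$first_year, x$last_year))
  cat(sprintf("  slope %+.3f %%/year (SE %.3f), R^2 = %.2f\n",
              x$slope, x$slope_se, x$r_squared))
  invisible(x)
}

#' Baseline (year-2000) coverage for a country
#'
#' If the series contains one or more surveys dated 2000, their mean is the
#' baseline and the source is `"survey_2000"`. Otherwise a caller-supplied
#' external (programme) estimate is used with source `"external_estimate"`.
#'
#' @param series a [coverage_series()].
#' @param external_estimate optional coverage percent used when no
#'   year-2000 survey exists.
#' @return list with `coverage_2000` and `baseline_source`.
#' @examples
#' s <- coverage_series("BGD", "water", c(2000, 2002), c(76.2, 78))
#' baseline_coverage(s)
#' @export
baseline_coverage <- function(series, external_estimate = NULL) {
  stopifnot(inherits(series, "coverage_series"))
  at2000 <- series$coverage[series$year == 2000L]
  if (length(at2000)) {
    return(list(coverage_2000 = mean(at2000), baseline_source = "survey_2000"))
  }
  if (is.null(external_estimate))
    stop_wf("series %s/%s has no year-2000 survey and no external estimate was supplied",
            attr(series, "country"), attr(series, "service"),
            class = "wf_missing_baseline_error")
  if (!is_scalar_number(external_estimate) ||
      external_estimate < 0 || external_estimate > 100)
    stop_wf("external baseline estimate must be a coverage percent in [0, 100]",
            class = "wf_validation_error")
  list(coverage_2000 = as.numeric(external_estimate),
       baseline_source = "external_estimate")
}

#' Estimate rates and baselines for many series
#'
#' Convenience wrapper running [apply_inclusion_filter()],
#' [estimate_rate()] and [baseline_coverage()] over a list of series.
#'
#' @param series_list list of [coverage_series()] objects.
#' @param external_baselines optional named numeric vector of programme
#'   estimates, named by country code, consulted when a series lacks a
#'   year-2000 survey.
#' @return data frame with one row per included series: `country`,
#'   `service`, `n_points`, `rate`, `rate_se`, `r_squared`,
#'   `coverage_2000`, `baseline_source`.
#' @export
estimate_rates <- function(series_list, external_baselines = NULL) {
  rows <- lapply(series_list, function(s) {
    dec <- apply_inclusion_filter(s)
    if (!dec$included) return(NULL)
    est <- estimate_rate(s)
    ext <- if (!is.null(external_baselines)) {
      unname(external_baselines[attr(s, "country")])
    } else NULL
    if (!is.null(ext) && is.na(ext)) ext <- NULL
    base <- baseline_coverage(s, ext)
    data.frame(country = est$country, service = est$service,
               n_points = est$n_points, rate = est$slope,
               rate_se = est$slope_se, r_squared = est$r_squared,
               coverage_2000 = base$coverage_2000,
               baseline_source = base$baseline_source,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(country = character(0), service = character(0),
                      n_points = integer(0), rate = numeric(0),
                      rate_se = numeric(0), r_squared = numeric(0),
                      coverage_2000 = numeric(0),
                      baseline_source = character(0))
  rownames(out) <- NULL
  out
}
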