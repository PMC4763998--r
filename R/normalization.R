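# The normalized rate of change: rate / max achievable rate at the
# country's baseline coverage, with the minimum rate pinned at zero.

#' Normalize an absolute rate of change against the frontier
#'
#' The normalized rate is `rate / max_rate(curve, coverage_2000)` — the
#' minimum rate of the scale is the constant zero (no progress) — clipped
#' to \[-1, 1\]. Two clamping rules apply:
#' * a raw ratio outside \[-1, 1\] is clipped to the nearer bound;
#' * a frontier member whose observed rate is at or above the fitted curve
#'   at its own coverage is assigned exactly 1: the least-squares curve can
#'   pass below the very points that define the frontier, and the
#'   countries that set the benchmark score full marks.
#'
#' Countries with negative rates keep the same ratio (still against the
#' maximum, there is no separate "worst performer" frontier), so the sign
#' of the normalized rate always matches the sign of the rate.
#'
#' @param estimate a [estimate_rate()] result, or a numeric rate (%/year).
#' @param coverage_2000 baseline coverage percent; required when
#'   `estimate` is numeric.
#' @param curve a `frontier_curve`.
#' @param frontier_member is this country one of the frontier points?
#' @param country optional identifier carried through.
#' @return Object of class `normalized_rate`: list with `country`,
#'   `value` (in \[-1, 1\]), `raw_value`, `clamped`, `frontier_member`,
#'   `max_rate`.
#' @examples
#' fc <- frontier_curve(c(0.04))        # linear frontier: 4 %/yr at zero coverage
#' normalize_rate(0.7, coverage_2000 = 30, curve = fc)$value  # 0.7 / 2.8
#' @export
normalize_rate <- function(estimate, coverage_2000 = NULL, curve,
                           frontier_member = FALSE, country = NULL) {
  if (inherits(estimate, "rate_estimate")) {
    slope <- estimate$slope
    country <- country %||% estimate$country
    if (is.null(coverage_2000))
      stop_wf("coverage_2000 is required (baseline is not part of a rate estimate)",
              class = "wf_parameter_error")
  } else {
    if (!is_scalar_number(estimate))
      stop_wf("estimate must be a rate_estimate or a single rate",
              class = "wf_parameter_error")
    slope <- estimate
  }
  stopifnot(inherits(curve, "frontier_curve"))
  mr <- max_rate(curve, coverage_2000)
  if (mr == 0)
    stop_wf("maximum achievable rate is 0 at coverage %g; the normalized rate is undefined",
            coverage_2000, class = "wf_undefined_normalization_error")
  raw <- slope / mr
  clamped <- FALSE
  value <- raw
  if (isTRUE(frontier_member) && slope >= mr) {
    value <- 1
    clamped <- TRUE
  } else if (raw > 1) {
    value <- 1; clamped <- TRUE
  } else if (raw < -1) {
    value <- -1; clamped <- TRUE
  }
  structure(list(country = country, value = value, raw_value = raw,
                 clamped = clamped, frontier_member = isTRUE(frontier_member),
                 max_rate = mr),
            class = "normalized_rate")
}

#' @export
print.normalized_rate <- function(x, ...) {
  cat(sprintf("Normalized rate%s: %.3f (raw %.3f, max rate %.3f%s%s)\n",
              if (is.null(x$country)) "" else paste0(" for ", x$country),
              x$value, x$raw_value, x$max_rate,
              if (x$clamped) ", clamped" else "",
              if (x$frontier_member) ", frontier member" else ""))
  invisible(x)
}

#' Normalize a table of rates against a fitted frontier
#'
#' Vectorized companion to [normalize_rate()] for pipeline use.
#'
#' @param points a [performance_points()] table with `is_frontier` (and
#'   optionally `is_outlier`) columns; outliers sitting above the curve
#'   are clamped to 1 exactly like frontier members, since they outperform
#'   the fitted maximum.
#' @param curve a `frontier_curve`.
#' @return `points` with added columns `max_rate`, `raw_value`,
#'   `normalized`, `clamped`.
#' @export
normalize_rates <- function(points, curve) {
  stopifnot(is.data.frame(points), inherits(curve, "frontier_curve"))
  mr <- max_rate(curve, points$coverage)
  if (any(mr == 0))
    stop_wf("maximum achievable rate is 0 at coverage %g",
            points$coverage[which(mr == 0)[1]],
            class = "wf_undefined_normalization_error")
  raw <- points$rate / mr
  above <- (isTRUE_col(points$is_frontier) | isTRUE_col(points$is_outlier)) &
    points$rate >= mr
  value <- pmin(pmax(raw, -1), 1)
  value[above] <- 1
  points$max_rate <- mr
  points$raw_value <- raw
  points$normalized <- value
  points$clamped <- above | raw > 1 | raw < -1
  points
}

#' Count countries above and below progress thresholds
#'
#' For each threshold `t`, counts normalized rates strictly below and
#' strictly above `t`. Strict inequality follows the reading of countries
#' "falling below" a benchmark: a country sitting exactly at the threshold
#' is in neither count.
#'
#' @param values numeric normalized rates (or a list of
#'   `normalized_rate` objects).
#' @param thresholds numeric vector of thresholds.
#' @return data frame with columns `threshold`, `n_below`, `n_above`,
#'   `n`, `frac_below`, `frac_above`.
#' @examples
#' summarize_progress(c(0.1, 0.25, 0.4, 0.9), thresholds = c(0.25, 0.5))
#' @export
summarize_progress <- function(values, thresholds) {
  if (is.list(values))
    values <- vapply(values, function(v) v$value, numeric(1))
  if (!length(values))
    stop_wf("no normalized rates to summarize", class = "wf_validation_error")
  if (!length(thresholds))
    return(data.frame(threshold = numeric(0), n_below = integer(0),
                      n_above = integer(0), n = integer(0),
                      frac_below = numeric(0), frac_above = numeric(0)))
  n <- length(values)
  data.frame(threshold = thresholds,
             n_below = vapply(thresholds, function(t) sum(values < t), integer(1)),
             n_above = vapply(thresholds, function(t) sum(values > t), integer(1)),
             n = n,
             frac_below = vapply(thresholds, function(t) mean(values < t), numeric(1)),
             frac_above = vapply(thresholds, function(t) mean(values > t), numeric(1)))
}
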