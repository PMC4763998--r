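# Best-performer frontier: outlier screening, frontier-point
# identification, and the constrained polynomial frontier curve.
#
# Working representation: a data frame of performance points with columns
#   country  - identifier
#   coverage - year-2000 baseline coverage, percent
#   rate     - absolute rate of change, %/year

#' Assemble a performance-point table
#'
#' @param country identifiers.
#' @param coverage baseline (year 2000) coverage, percent in \[0, 100\].
#' @param rate absolute rates of change, %/year.
#' @return data frame with columns `country`, `coverage`, `rate` and
#'   logical columns `is_outlier`, `is_frontier` initialized to `FALSE`.
#' @export
performance_points <- function(country, coverage, rate) {
  stopifnot(length(country) == length(coverage),
            length(coverage) == length(rate))
  if (any(coverage < 0 | coverage > 100, na.rm = TRUE))
    stop_wf("baseline coverage must lie in [0, 100]", class = "wf_validation_error")
  data.frame(country = country, coverage = as.numeric(coverage),
             rate = as.numeric(rate), is_outlier = FALSE,
             is_frontier = FALSE, stringsAsFactors = FALSE)
}

#' Flag outliers among candidate frontier points
#'
#' Two mechanisms, both recorded in an `outlier_method` column:
#' a manual list (always honoured, used to reproduce the benchmark
#' analysis, where Mali is excluded from the water frontier), and an
#' automated one-sided Grubbs test on the candidate rates at level
#' `alpha`, applied to the maximum rate. The Grubbs statistic is
#' `G = (max(r) - mean(r)) / sd(r)` and the critical value is the usual
#' t-based bound `((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/n, n - 2)`.
#'
#' @param points a [performance_points()] table; only rows considered
#'   candidates (positive rate, see [identify_frontier_points()]) inform
#'   the Grubbs statistic, which needs at least 3 candidates.
#' @param alpha significance level in (0, 1) for the Grubbs test, or
#'   `NULL` to skip the statistical rule.
#' @param manual_list character vector of country identifiers flagged
#'   unconditionally.
#' @return `points` with `is_outlier` and `outlier_method`
#'   (`"manual"`, `"grubbs"` or `NA`) filled in.
#' @export
flag_outliers <- function(points, alpha = 0.05, manual_list = NULL) {
  stopifnot(is.data.frame(points))
  if (!is.null(alpha) && (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1))
    stop_wf("alpha must lie strictly between 0 and 1", class = "wf_parameter_error")
  points$is_outlier <- FALSE
  points$outlier_method <- NA_character_
  if (length(manual_list)) {
    hit <- points$country %in% manual_list
    points$is_outlier[hit] <- TRUE
    points$outlier_method[hit] <- "manual"
  }
  if (!is.null(alpha)) {
    cand <- which(!points$is_outlier & points$rate > 0)
    # repeat: the test is for a single largest-value outlier, so re-test
    # after each removal until nothing more is flagged
    repeat {
      if (length(cand) < 3L) break
      r <- points$rate[cand]
      if (sd(r) == 0) break
      g <- grubbs_statistic(r)
      if (g$statistic <= grubbs_critical(length(r), alpha)) break
      i <- cand[g$index]
      points$is_outlier[i] <- TRUE
      points$outlier_method[i] <- "grubbs"
      cand <- setdiff(cand, i)
    }
  }
  points
}

grubbs_statistic <- function(x) {
  i <- which.max(x)
  list(statistic = (x[i] - mean(x)) / sd(x), index = i)
}

grubbs_critical <- function(n, alpha) {
  t <- qt(1 - alpha / n, n - 2)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Identify best-performing frontier points
#'
#' Candidates are points that are not flagged as outliers and have a
#' strictly positive rate: with the minimum rate pinned at zero, the
#' frontier describes maximum positive progress, and stagnating or
#' regressing high-coverage countries do not belong on it.
#'
#' Methods:
#' \describe{
#'   \item{`upper_convex_hull`}{(default) a candidate is a frontier point
#'     iff it is a vertex of the upper convex hull of the candidates in
#'     the (coverage, rate) plane, endpoints included.}
#'   \item{`pareto_dominance`}{a candidate is a frontier point iff no
#'     other candidate has lower-or-equal coverage and strictly greater
#'     rate (free-disposal style boundary).}
#'   \item{`explicit_list`}{the caller names the frontier countries; used
#'     to reproduce published frontier sets that no algorithm recovers
#'     exactly.}
#' }
#'
#' @param points a [performance_points()] table, optionally already
#'   through [flag_outliers()].
#' @param method see above.
#' @param explicit character vector of frontier countries, required for
#'   `explicit_list`.
#' @return `points` with `is_frontier` filled in.
#' @examples
#' pts <- performance_points(c("A", "B", "C"), c(30, 60, 90), c(2.5, 2, 0.5))
#' identify_frontier_points(pts)$is_frontier
#' @export
identify_frontier_points <- function(points,
                                     method = c("upper_convex_hull",
                                                "pareto_dominance",
                                                "explicit_list"),
                                     explicit = NULL) {
  method <- match.arg(method)
  stopifnot(is.data.frame(points))
  points$is_frontier <- FALSE
  if (method == "explicit_list") {
    if (is.null(explicit))
      stop_wf("method 'explicit_list' needs the frontier countries",
              class = "wf_parameter_error")
    points$is_frontier <- points$country %in% explicit
    return(points)
  }
  cand <- which(!points$is_outlier & points$rate > 0)
  if (!length(cand))
    stop_wf("no candidate points (positive rate, non-outlier) to build a frontier from",
            class = "wf_no_frontier_error")
  x <- points$coverage[cand]
  y <- points$rate[cand]
  onf <- switch(method,
                upper_convex_hull = upper_hull_vertices(x, y),
                pareto_dominance  = pareto_frontier(x, y))
  points$is_frontier[cand[onf]] <- TRUE
  points
}

# Andrew's monotone chain, upper hull only. Strict turns: collinear
# interior points are not vertices. Returns indices into (x, y).
upper_hull_vertices <- function(x, y) {
  n <- length(x)
  if (n == 1L) return(1L)
  o <- order(x, -y)
  xs <- x[o]; ys <- y[o]
  h <- integer(0)
  for (k in seq_len(n)) {
    while (length(h) >= 2L) {
      i <- h[length(h) - 1L]; j <- h[length(h)]
      # cross product of (i -> j) x (i -> k); >= 0 means j does not make
      # a strict right (downward-convex) turn and is popped
      cr <- (xs[j] - xs[i]) * (ys[k] - ys[i]) - (ys[j] - ys[i]) * (xs[k] - xs[i])
      if (cr >= 0) h <- h[-length(h)] else break
    }
    h <- c(h, k)
  }
  # duplicate-x columns: keep only the highest point at each x
  keep <- !duplicated(data.frame(xs[h]))
  sort(o[h[keep]])
}

pareto_frontier <- function(x, y) {
  keep <- vapply(seq_along(x), function(i) {
    !any(x <= x[i] & y > y[i])
  }, logical(1))
  which(keep)
}

#' Fit the maximum-achievable-rate frontier curve
#'
#' Least-squares fit of frontier rates on the polynomial basis
#' `u, u^2, ..., u^degree` with `u = 100 - coverage` and no constant term.
#' The missing intercept enforces exactly the structural constraint that a
#' country at 100% coverage can progress no further: the curve passes
#' through (coverage = 100, rate = 0). Because the fit is least squares
#' under that constraint, the curve may fall below individual frontier
#' points (negative residuals); such countries are handled by the
#' frontier-member rule in [normalize_rate()].
#'
#' @param points a [performance_points()] table with `is_frontier` set
#'   (see [identify_frontier_points()]), or any data frame of frontier
#'   points with `coverage` and `rate` columns if `use_all = TRUE`.
#' @param degree polynomial degree, 1 to 5; default 3, the lowest degree
#'   that tracks the concave-then-flat empirical frontier shape for both
#'   services.
#' @param service optional label carried in the object.
#' @param use_all fit to all rows instead of the `is_frontier` subset.
#' @return Object of class `frontier_curve` with elements `coefficients`
#'   (named `u`, `u^2`, ...), `degree`, `service`, `support` (the points
#'   used), `fitted`, `residuals`.
#' @examples
#' pts <- performance_points("A", 50, 2)
#' pts$is_frontier <- TRUE
#' fc <- fit_frontier(pts, degree = 1)
#' max_rate(fc, 75)  # 1.0 by linear interpolation towards (100, 0)
#' @export
fit_frontier <- function(points, degree = 3, service = NULL, use_all = FALSE) {
  stopifnot(is.data.frame(points))
  if (!is_scalar_number(degree) || degree < 1 || degree > 5 ||
      degree != round(degree))
    stop_wf("degree must be an integer between 1 and 5", class = "wf_parameter_error")
  degree <- as.integer(degree)
  fp <- if (use_all) points else points[isTRUE_col(points$is_frontier), , drop = FALSE]
  if (nrow(fp) < degree)
    stop_wf("%d frontier point(s) cannot determine a degree-%d curve",
            nrow(fp), degree, class = "wf_underdetermined_fit_error")
  u <- 100 - fp$coverage
  X <- outer(u, seq_len(degree), `^`)
  colnames(X) <- poly_names(degree)
  fit <- lm.fit(X, fp$rate)
  beta <- setNames(fit$coefficients, colnames(X))
  if (anyNA(beta))
    stop_wf("frontier design is rank-deficient (coincident coverages?)",
            class = "wf_underdetermined_fit_error")
  structure(list(coefficients = beta, degree = degree,
                 service = service, support = fp,
                 fitted = unname(fit$fitted.values),
                 residuals = unname(fit$residuals)),
            class = "frontier_curve")
}

isTRUE_col <- function(x) if (is.null(x)) logical(0) else x %in% TRUE

poly_names <- function(degree) {
  ifelse(seq_len(degree) == 1L, "u", paste0("u^", seq_len(degree)))
}

#' Build a frontier curve from known coefficients
#'
#' Used mainly by the synthetic-data generator, where the true frontier is
#' specified rather than fitted.
#'
#' @param coefficients numeric vector of coefficients on
#'   `u, u^2, ..., u^degree`, `u = 100 - coverage`.
#' @param service optional label.
#' @return `frontier_curve` object without fit support.
#' @export
frontier_curve <- function(coefficients, service = NULL) {
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1)
  structure(list(coefficients = setNames(as.numeric(coefficients),
                                         poly_names(length(coefficients))),
                 degree = length(coefficients), service = service,
                 support = NULL, fitted = NULL, residuals = NULL),
            class = "frontier_curve")
}

#' Maximum achievable rate at a coverage level
#'
#' Evaluates the frontier polynomial at `u = 100 - coverage`, clipped
#' below at zero: a negative "maximum achievable rate" has no meaning in
#' the normalization. No clipping is applied above. At coverage 100 the
#' curve is exactly 0 by construction.
#'
#' @param curve a `frontier_curve`.
#' @param coverage coverage percent(s) in \[0, 100\].
#' @return numeric vector of maximum rates, %/year.
#' @export
max_rate <- function(curve, coverage) {
  stopifnot(inherits(curve, "frontier_curve"))
  if (any(coverage < 0 | coverage > 100, na.rm = TRUE))
    stop_wf("coverage must lie in [0, 100]", class = "wf_domain_error")
  u <- 100 - coverage
  raw <- drop(outer(u, seq_len(curve$degree), `^`) %*% curve$coefficients)
  pmax(raw, 0)
}

#' @export
#' @rdname max_rate
#' @param object a `frontier_curve`.
#' @param clip clip negative evaluations to zero (default `TRUE`).
#' @param ... unused.
predict.frontier_curve <- function(object, coverage, clip = TRUE, ...) {
  if (!clip) {
    u <- 100 - coverage
    return(drop(outer(u, seq_len(object$degree), `^`) %*% object$coefficients))
  }
  max_rate(object, coverage)
}

#' @export
coef.frontier_curve <- function(object, ...) object$coefficients

#' @export
residuals.frontier_curve <- function(object, ...) object$residuals

#' @export
print.frontier_curve <- function(x, ...) {
  lab <- if (is.null(x$service)) "" else paste0(" (", x$service, ")")
  cat(sprintf("Frontier curve%s: degree %d in u = 100 - coverage, r(100) = 0\n",
              lab, x$degree))
  print(round(x$coefficients, 6))
  if (!is.null(x$support))
    cat(sprintf("Fitted to %d frontier point(s)\n", nrow(x$support)))
  invisible(x)
}

#' @export
summary.frontier_curve <- function(object, ...) {
  print(object)
  if (!is.null(object$support)) {
    cat("Support points:\n")
    print(data.frame(country = object$support$country,
                     coverage = object$support$coverage,
                     rate = object$support$rate,
                     fitted = round(object$fitted, 3),
                     residual = round(object$residuals, 3)))
  }
  grid <- seq(0, 100, by = 5)
  cat("Maximum achievable rate on a coverage grid:\n")
  print(setNames(round(max_rate(object, grid), 3), grid))
  invisible(object)
}

#' Plot performance points and the fitted frontier curve
#'
#' @param x a `frontier_curve`.
#' @param points optional full [performance_points()] table to show
#'   alongside the support points.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.frontier_curve <- function(x, points = NULL, ...) {
  cov_grid <- seq(0, 100, length.out = 401)
  rates <- max_rate(x, cov_grid)
  all_pts <- points %||% x$support
  ylim <- range(0, rates, all_pts$rate, na.rm = TRUE)
  plot(cov_grid, rates, type = "l", lwd = 2,
       xlab = "Coverage in 2000 (%)",
       ylab = "Rate of change (percentage points / year)",
       ylim = ylim, ...)
  if (!is.null(points)) {
    col <- ifelse(isTRUE_col(points$is_outlier), "red",
                  ifelse(isTRUE_col(points$is_frontier), "blue", "grey40"))
    pch <- ifelse(isTRUE_col(points$is_frontier), 19, 1)
    points(points$coverage, points$rate, col = col, pch = pch)
    legend("topright", bty = "n", pch = c(19, 1, 1),
           col = c("blue", "grey40", "red"),
           legend = c("frontier", "other", "outlier"))
  } else if (!is.null(x$support)) {
    points(x$support$coverage, x$support$rate, pch = 19, col = "blue")
  }
  invisible(x)
}
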