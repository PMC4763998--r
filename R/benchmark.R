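# One-call reproduction of the benchmark 73-country analysis from the
# packaged progress table.

#' Reproduce the benchmark frontier analysis for one service
#'
#' Runs the full frontier workflow on the packaged 73-country table:
#' assemble (baseline coverage, rate) points, flag outliers (Mali, for
#' water, by the documented manual list), identify frontier points — the
#' upper convex hull for water, which recovers Armenia, Egypt, Ethiopia,
#' Ghana and Samoa; the documented explicit eight-country list for
#' sanitation, whose published set no hull algorithm reproduces — fit the
#' constrained polynomial frontier curve, and normalize every country's
#' rate.
#'
#' @param service `"water"` or `"sanitation"`.
#' @param degree frontier polynomial degree (default 3).
#' @param method frontier identification method; defaults to
#'   `"upper_convex_hull"` for water and `"explicit_list"` for sanitation.
#' @return list with elements `service`, `table` (the service block of the
#'   progress table), `points` (performance points with outlier/frontier
#'   flags and normalized rates), `curve` (the fitted `frontier_curve`)
#'   and `summary` (threshold counts at 0.25 and 0.5).
#' @examples
#' bench <- frontier_benchmark("water")
#' bench$points$country[bench$points$is_frontier]
#' @export
frontier_benchmark <- function(service = c("water", "sanitation"),
                               degree = 3, method = NULL) {
  service <- match.arg(service)
  tab <- progress_table_service(load_progress_table(), service)
  sets <- benchmark_frontier_sets(service)
  pts <- performance_points(tab$iso3, tab$coverage_2000, tab$rate)
  pts$name <- tab$country
  pts <- flag_outliers(pts, alpha = NULL, manual_list = sets$outliers)
  method <- method %||%
    if (service == "water") "upper_convex_hull" else "explicit_list"
  pts <- identify_frontier_points(pts, method = method,
                                  explicit = sets$frontier)
  curve <- fit_frontier(pts, degree = degree, service = service)
  pts <- normalize_rates(pts, curve)
  list(service = service, table = tab, points = pts, curve = curve,
       summary = summarize_progress(pts$normalized, c(0.25, 0.5)))
}
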