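# Packaged benchmark tables: the 73-country coverage-trend table and the
# discordant country pairings, transcribed at printed precision.

#' Load the packaged 73-country progress table
#'
#' The benchmark table gives, for each of 73 countries and each service
#' (drinking water, sanitation): the number of survey data points, the year
#' range, the R-squared of the linear trend, year-2000 baseline coverage,
#' the absolute rate of change (percentage points per year) and the
#' normalized rate of change. 67 countries have a water block and 61 a
#' sanitation block. `*_baseline_external` marks baselines taken from
#' programme estimates rather than a year-2000 survey.
#'
#' The printed value "-0.00" (a negative estimate rounded to zero) is
#' stored as 0.0 and is treated as non-positive wherever positivity
#' matters, e.g. for frontier candidacy.
#'
#' @return data frame of class `benchmark` with 73 rows.
#' @examples
#' tab <- load_progress_table()
#' nrow(tab)
#' sum(!is.na(tab$water_rate))
#' @export
load_progress_table <- function() {
  path <- system.file("extdata", "progress_benchmark.csv",
                      package = "washfrontier", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  ok <- nrow(df) == 73L &&
    sum(!is.na(df$water_rate)) == 67L &&
    sum(!is.na(df$san_rate)) == 61L &&
    all(abs(df$water_normalized) <= 1, na.rm = TRUE) &&
    all(abs(df$san_normalized) <= 1, na.rm = TRUE)
  if (!ok)
    stop_wf("packaged progress table failed its integrity checks",
            class = "wf_fixture_error")
  class(df) <- c("benchmark", "data.frame")
  df
}

#' Extract one service block from the progress table
#'
#' @param tab table from [load_progress_table()].
#' @param service `"water"` or `"sanitation"`.
#' @return data frame with columns `country`, `iso3`, `n_points`,
#'   `year_first`, `year_last`, `r_squared`, `coverage_2000`, `rate`,
#'   `normalized`, `baseline_external`; one row per country with data for
#'   that service.
#' @export
progress_table_service <- function(tab, service = c("water", "sanitation")) {
  service <- match.arg(service)
  p <- if (service == "water") "water_" else "san_"
  cols <- paste0(p, c("n", "year_first", "year_last", "r2", "coverage_2000",
                      "rate", "normalized", "baseline_external"))
  out <- tab[!is.na(tab[[paste0(p, "rate")]]),
             c("country", "iso3", cols)]
  names(out) <- c("country", "iso3", "n_points", "year_first", "year_last",
                  "r_squared", "coverage_2000", "rate", "normalized",
                  "baseline_external")
  rownames(out) <- NULL
  out
}

#' Frontier membership and outliers used in the benchmark analysis
#'
#' For water, the five frontier countries are recovered algorithmically as
#' the upper convex hull of the positive-rate points once the outlier
#' (Mali) is removed. For sanitation the eight-country frontier set is not
#' an exact convex hull (Sri Lanka lies marginally inside it) and the
#' identification algorithm that produced it cannot be inferred, so
#' reproduction runs supply it as an explicit list.
#'
#' @param service `"water"` or `"sanitation"`.
#' @return list with character vectors `frontier` (ISO-3 codes) and
#'   `outliers`.
#' @export
benchmark_frontier_sets <- function(service = c("water", "sanitation")) {
  service <- match.arg(service)
  if (service == "water")
    list(frontier = c("ARM", "EGY", "ETH", "GHA", "WSM"),
         outliers = "MLI")
  else
    list(frontier = c("BEN", "EGY", "EST", "ETH", "HND", "LAO", "RWA", "LKA"),
         outliers = character(0))
}

#' Load the packaged discordant country pairings
#'
#' Pairs of countries from the same geographic region and country cluster
#' with similar baseline coverage but markedly different normalized rates,
#' together with five socioeconomic indicators for each.
#'
#' @param service `"water"`, `"sanitation"` or `"both"` (default).
#' @return data frame with one row per country per pair.
#' @export
load_pairings <- function(service = c("both", "water", "sanitation")) {
  service <- match.arg(service)
  path <- system.file("extdata", "country_pairings.csv",
                      package = "washfrontier", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (service != "both") df <- df[df$service == service, , drop = FALSE]
  rownames(df) <- NULL
  df
}
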