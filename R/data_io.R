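# Reading, validating and writing coverage series and indicator tables.

#' Construct a coverage time series for one country and service
#'
#' A coverage series holds the survey observations of national coverage
#' (percent of population with access to an improved facility) for one
#' country and one service. Observations before year 2000 are not accepted:
#' progress is measured from the year the Millennium Development Goals were
#' set. Several observations in the same year are legitimate (different
#' surveys) and are kept as independent points.
#'
#' @param country ISO-3 country code (or any stable identifier).
#' @param service `"water"` or `"sanitation"`.
#' @param year integer calendar years, all >= 2000.
#' @param coverage numeric coverage values in percent, within \[0, 100\].
#' @return An object of class `coverage_series`: a data frame of
#'   observations (`year`, `coverage`) with `country` and `service`
#'   attributes.
#' @examples
#' s <- coverage_series("KEN", "water", 2000:2004, c(50, 51, 52, 53, 54))
#' nrow(s)
#' @export
coverage_series <- function(country, service, year, coverage) {
  service <- match.arg(service, c("water", "sanitation"))
  if (length(year) != length(coverage) || length(year) == 0L)
    stop_wf("a coverage series needs matching, non-empty year and coverage vectors",
            class = "wf_validation_error")
  year <- as.integer(year)
  if (anyNA(year) || anyNA(coverage))
    stop_wf("missing year or coverage values in series %s/%s", country, service,
            class = "wf_validation_error")
  if (any(year < 2000L))
    stop_wf("series %s/%s contains observations before 2000", country, service,
            class = "wf_validation_error")
  bad <- which(coverage < 0 | coverage > 100)
  if (length(bad))
    stop_wf("coverage outside [0, 100] in series %s/%s at row %d (value %g)",
            country, service, bad[1], coverage[bad[1]],
            class = "wf_validation_error")
  obs <- data.frame(year = year, coverage = as.numeric(coverage))
  obs <- obs[order(obs$year), , drop = FALSE]
  rownames(obs) <- NULL
  structure(obs, country = country, service = service,
            class = c("coverage_series", "data.frame"))
}

#' @export
print.coverage_series <- function(x, ...) {
  cat(sprintf("Coverage series: %s / %s, %d observation(s), %d-%d\n",
              attr(x, "country"), attr(x, "service"), nrow(x),
              min(x$year), max(x$year)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Load coverage series from a CSV file
#'
#' Expects columns `country,service,year,coverage`. Rows dated before 2000
#' are dropped with a warning; duplicate years are retained as independent
#' observations. Coverage values outside \[0, 100\] abort the load, naming
#' the offending row.
#'
#' @param path path to a CSV file.
#' @return A named list of [coverage_series()] objects, one per
#'   (country, service), named `"<country>.<service>"`.
#' @export
load_coverage_series <- function(path) {
  if (!file.exists(path))
    stop_wf("coverage file not found: %s", path, class = "wf_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "service", "year", "coverage")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_wf("coverage file %s is missing column(s): %s", path,
            paste(miss, collapse = ", "), class = "wf_format_error")
  df$year <- as.integer(df$year)
  df$coverage <- as.numeric(df$coverage)
  bad <- which(is.na(df$coverage) | df$coverage < 0 | df$coverage > 100)
  if (length(bad))
    stop_wf("coverage outside [0, 100] at data row %d of %s", bad[1], path,
            class = "wf_validation_error")
  pre <- df$year < 2000L
  if (any(pre)) {
    warning(sprintf("dropping %d observation(s) before year 2000 from %s",
                    sum(pre), path))
    df <- df[!pre, , drop = FALSE]
  }
  if (!nrow(df))
    stop_wf("no usable observations (year >= 2000) in %s", path,
            class = "wf_validation_error")
  key <- paste(df$country, df$service, sep = ".")
  out <- lapply(split(df, key), function(d)
    coverage_series(d$country[1], d$service[1], d$year, d$coverage))
  out[order(names(out))]
}

#' Apply the study inclusion filter to a coverage series
#'
#' A country-service series is retained for rate estimation only if it has
#' at least five survey data points covering at least three distinct years.
#'
#' @param series a [coverage_series()].
#' @return A list of class `inclusion_decision` with elements `country`,
#'   `service`, `included`, `reason` (empty string when included),
#'   `n_points` and `n_years`.
#' @examples
#' s <- coverage_series("KEN", "water", 2000:2004, c(50, 51, 52, 53, 54))
#' apply_inclusion_filter(s)$included
#' @export
apply_inclusion_filter <- function(series) {
  stopifnot(inherits(series, "coverage_series"))
  n <- nrow(series)
  ny <- length(unique(series$year))
  reason <- character(0)
  if (n < 5L) reason <- c(reason, sprintf("fewer than 5 points (%d)", n))
  if (ny < 3L) reason <- c(reason, sprintf("fewer than 3 distinct years (%d)", ny))
  structure(list(country = attr(series, "country"),
                 service = attr(series, "service"),
                 included = length(reason) == 0L,
                 reason = paste(reason, collapse = "; "),
                 n_points = n, n_years = ny),
            class = "inclusion_decision")
}

#' @export
print.inclusion_decision <- function(x, ...) {
  cat(sprintf("%s/%s: %s%s\n", x$country, x$service,
              if (x$included) "included" else "excluded",
              if (x$included) "" else paste0(" (", x$reason, ")")))
  invisible(x)
}

#' Summarize inclusion decisions for a set of series
#'
#' @param series_list list of [coverage_series()] objects.
#' @return data frame with one row per series.
#' @export
inclusion_table <- function(series_list) {
  rows <- lapply(series_list, function(s) {
    d <- apply_inclusion_filter(s)
    data.frame(country = d$country, service = d$service,
               included = d$included, reason = d$reason,
               n_points = d$n_points, n_years = d$n_years,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# canonical socioeconomic indicator column names
WF_INDICATORS <- c("gni_per_capita", "government_effectiveness",
                   "oda_per_capita", "freshwater_per_capita",
                   "female_secondary_education", "poverty_headcount",
                   "gini", "under5_mortality", "hdi")

#' Load a national socioeconomic indicator table
#'
#' Reads a CSV with a `country` column plus any subset of the nine
#' indicators used in the association analysis: per-capita gross national
#' income (`gni_per_capita`), government effectiveness
#' (`government_effectiveness`), per-capita official development
#' assistance for water and sanitation (`oda_per_capita`), per-capita
#' renewable internal freshwater (`freshwater_per_capita`), female
#' secondary-education completion (`female_secondary_education`), poverty
#' headcount below US$ 1.25/day (`poverty_headcount`), Gini coefficient
#' (`gini`), under-five mortality (`under5_mortality`) and the human
#' development index (`hdi`). Unknown columns are dropped with a warning;
#' missing cells are allowed and recorded in the availability mask.
#'
#' @param path path to a CSV file.
#' @return data frame of class `indicator_matrix` keyed by `country`, with
#'   all nine indicator columns (absent ones all-`NA`) and an `available`
#'   attribute (logical matrix marking non-missing cells).
#' @export
load_indicator_table <- function(path) {
  if (!file.exists(path))
    stop_wf("indicator file not found: %s", path, class = "wf_io_error")
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   data.frame(country = character(0), stringsAsFactors = FALSE))
  if (!"country" %in% names(df) && !ncol(df))
    df$country <- character(0)
  if (!"country" %in% names(df))
    stop_wf("indicator file %s has no 'country' column", path,
            class = "wf_format_error")
  unknown <- setdiff(names(df), c("country", WF_INDICATORS))
  if (length(unknown)) {
    warning(sprintf("ignoring unknown indicator column(s): %s",
                    paste(unknown, collapse = ", ")))
    df <- df[, setdiff(names(df), unknown), drop = FALSE]
  }
  for (ind in WF_INDICATORS)
    df[[ind]] <- if (ind %in% names(df)) as.numeric(df[[ind]])
                 else rep(NA_real_, nrow(df))
  df <- df[, c("country", WF_INDICATORS)]
  validate_indicator_ranges(df)
  avail <- !is.na(as.matrix(df[, WF_INDICATORS]))
  rownames(avail) <- df$country
  structure(df, available = avail,
            class = c("indicator_matrix", "data.frame"))
}

validate_indicator_ranges <- function(df) {
  chk <- function(col, lo, hi) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < lo | v > hi))
    if (length(bad))
      stop_wf("%s outside [%g, %g] for country %s", col, lo, hi,
              df$country[bad[1]], class = "wf_validation_error")
  }
  chk("female_secondary_education", 0, 100)
  chk("poverty_headcount", 0, 100)
  chk("gini", 0, 100)
  chk("hdi", 0, 1)
  invisible(df)
}

#' Write pipeline results to CSV
#'
#' Writes the standard results schema
#' `country,service,n_points,rate,rate_se,r_squared,coverage_2000,`
#' `normalized_rate,clamped,frontier_member` with full numeric precision,
#' so that a write/load round trip is exact.
#'
#' @param results data frame in the results schema.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [load_results()]
#' @export
write_results <- function(results, path) {
  write.csv(format_results(results), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

format_results <- function(results) {
  num <- vapply(results, is.numeric, logical(1))
  results[num] <- lapply(results[num], function(x) {
    # 17 significant digits preserve doubles exactly through text
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  })
  results
}

#' Load pipeline results written by [write_results()]
#'
#' @param path path to a results CSV.
#' @return data frame with numeric columns restored at full precision.
#' @export
load_results <- function(path) {
  if (!file.exists(path))
    stop_wf("results file not found: %s", path, class = "wf_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("rate", "rate_se", "r_squared",
                          "coverage_2000", "normalized_rate"), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  if ("n_points" %in% names(df)) df$n_points <- as.integer(df$n_points)
  for (col in intersect(c("clamped", "frontier_member"), names(df)))
    df[[col]] <- as.logical(df[[col]])
  df
}
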