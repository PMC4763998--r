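# End-to-end pipeline driver: validated config in, results bundle and
# CSV outputs (plus a run manifest) out.

wf_config_defaults <- function() {
  list(input = list(rates = NULL, coverage = NULL, baselines = NULL,
                    indicators = NULL),
       service = "water",
       frontier = list(method = "upper_convex_hull", degree = 3L,
                       explicit = NULL),
       outliers = list(mode = "manual", manual = list(), alpha = 0.05),
       thresholds = c(0.25, 0.5),
       conflict_list = NULL,
       run_associations = FALSE,
       output_dir = NULL,
       seed = 1L)
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a list; fills in defaults and checks every
#' constraint, collecting all violations into a single error. Keys:
#' `input` (`rates` = `"benchmark"` or a rates CSV, or `coverage` = survey
#' CSV, plus optional `baselines` and `indicators` CSVs), `service`,
#' `frontier` (`method`, `degree` 1-5, `explicit`), `outliers` (`mode` =
#' `"manual"`/`"grubbs"`/`"none"`, `manual`, `alpha`), `thresholds`,
#' `conflict_list` (file or vector), `run_associations`, `output_dir`,
#' `seed`. Unknown keys are an error.
#'
#' @param config file path or list.
#' @return validated config of class `pipeline_config`, with all defaults
#'   materialized.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop_wf("config file not found: %s", config, class = "wf_io_error")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- wf_config_defaults()
  errs <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errs <- c(errs, sprintf("unknown key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config)
  for (sub in c("input", "frontier", "outliers")) {
    bad <- setdiff(names(config[[sub]]), names(defaults[[sub]]))
    if (length(bad))
      errs <- c(errs, sprintf("unknown key(s) under '%s': %s", sub,
                              paste(bad, collapse = ", ")))
  }
  if (!cfg$service %in% c("water", "sanitation"))
    errs <- c(errs, "service must be 'water' or 'sanitation'")
  d <- cfg$frontier$degree
  if (!is_scalar_number(d) || d < 1 || d > 5 || d != round(d))
    errs <- c(errs, "frontier.degree must be an integer in [1, 5]")
  if (!cfg$frontier$method %in% c("upper_convex_hull", "pareto_dominance",
                                  "explicit_list"))
    errs <- c(errs, "unknown frontier.method")
  if (cfg$frontier$method == "explicit_list" &&
      !length(cfg$frontier$explicit) && !identical(cfg$input$rates, "benchmark"))
    errs <- c(errs, "frontier.method 'explicit_list' needs frontier.explicit")
  if (!cfg$outliers$mode %in% c("manual", "grubbs", "none"))
    errs <- c(errs, "outliers.mode must be 'manual', 'grubbs' or 'none'")
  a <- cfg$outliers$alpha
  if (!is_scalar_number(a) || a <= 0 || a >= 1)
    errs <- c(errs, "outliers.alpha must lie in (0, 1)")
  has_rates <- !is.null(cfg$input$rates)
  has_cov <- !is.null(cfg$input$coverage)
  if (!has_rates && !has_cov)
    errs <- c(errs, "input needs either 'rates' ('benchmark' or a CSV) or 'coverage'")
  for (key in c("rates", "coverage", "baselines", "indicators")) {
    p <- cfg$input[[key]]
    if (!is.null(p) && !identical(p, "benchmark") && !file.exists(p))
      errs <- c(errs, sprintf("input.%s path does not exist: %s", key, p))
  }
  if (is.character(cfg$conflict_list) && length(cfg$conflict_list) == 1L &&
      grepl("\\.(txt|csv)$", cfg$conflict_list)) {
    if (!file.exists(cfg$conflict_list))
      errs <- c(errs, sprintf("conflict_list file does not exist: %s",
                              cfg$conflict_list))
    else cfg$conflict_list <- readLines(cfg$conflict_list, warn = FALSE)
  }
  if (length(errs))
    stop_wf("invalid pipeline config:\n  - %s", paste(errs, collapse = "\n  - "),
            class = "wf_config_error")
  cfg$frontier$degree <- as.integer(cfg$frontier$degree)
  cfg$seed <- as.integer(cfg$seed)
  cfg$outliers$manual <- as.character(unlist(cfg$outliers$manual))
  structure(cfg, class = "pipeline_config")
}

#' Run the full progress-measurement pipeline
#'
#' Orchestrates the stages: acquire country rates (from the packaged
#' progress table, a precomputed rates CSV, or raw survey series put
#' through the inclusion filter and OLS), flag outliers, identify
#' frontier points, fit the constrained frontier curve, normalize all
#' rates, summarize against thresholds, and (optionally) run the
#' indicator association stage. All stage outputs are written as CSV to
#' `output_dir` (when set) together with a `manifest.yaml` echoing the
#' materialized config; re-running the same config reproduces the result
#' CSVs byte-identically.
#'
#' @param config a [validate_config()]-ready list, path, or validated
#'   `pipeline_config`.
#' @return (invisibly printed) list of class `pipeline_result` with
#'   `config`, `points`, `curve`, `results`, `summary`, `models`, `log`.
#' @export
run_full_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  set.seed(config$seed)
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message("[washfrontier] ", msg)
    log <<- c(log, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_wf("pipeline stage '%s' failed: %s", name, conditionMessage(e),
              class = "wf_stage_error"))
  }

  # --- rates ----------------------------------------------------------
  rates <- stage("rates", {
    if (identical(config$input$rates, "benchmark")) {
      tab <- progress_table_service(load_progress_table(), config$service)
      data.frame(country = tab$iso3, name = tab$country,
                 service = config$service, n_points = tab$n_points,
                 rate = tab$rate, rate_se = NA_real_,
                 r_squared = tab$r_squared,
                 coverage_2000 = tab$coverage_2000,
                 baseline_source = ifelse(tab$baseline_external,
                                          "external_estimate", "survey_2000"),
                 stringsAsFactors = FALSE)
    } else if (!is.null(config$input$rates)) {
      df <- read.csv(config$input$rates, stringsAsFactors = FALSE)
      need <- c("country", "coverage_2000", "rate")
      miss <- setdiff(need, names(df))
      if (length(miss))
        stop_wf("rates file is missing column(s): %s",
                paste(miss, collapse = ", "), class = "wf_format_error")
      df$service <- df$service %||% config$service
      df
    } else {
      series <- load_coverage_series(config$input$coverage)
      series <- Filter(function(s) attr(s, "service") == config$service, series)
      ext <- NULL
      if (!is.null(config$input$baselines)) {
        b <- read.csv(config$input$baselines, stringsAsFactors = FALSE)
        ext <- setNames(b$coverage_2000, b$country)
      }
      estimate_rates(series, external_baselines = ext)
    }
  })
  say("rates: %d countr%s with estimates for %s", nrow(rates),
      if (nrow(rates) == 1) "y" else "ies", config$service)

  # --- frontier -------------------------------------------------------
  pts <- performance_points(rates$country, rates$coverage_2000, rates$rate)
  pts <- stage("outliers", switch(config$outliers$mode,
    manual = flag_outliers(pts, alpha = NULL,
                           manual_list = benchmark_outliers(config)),
    grubbs = flag_outliers(pts, alpha = config$outliers$alpha,
                           manual_list = config$outliers$manual),
    none = flag_outliers(pts, alpha = NULL, manual_list = NULL)))
  say("outliers: %d flagged", sum(pts$is_outlier))
  explicit <- config$frontier$explicit
  if (config$frontier$method == "explicit_list" && !length(explicit))
    explicit <- benchmark_frontier_sets(config$service)$frontier
  pts <- stage("frontier",
               identify_frontier_points(pts, method = config$frontier$method,
                                        explicit = explicit))
  say("frontier: %d point(s) [%s]", sum(pts$is_frontier), config$frontier$method)
  curve <- stage("curve_fit",
                 fit_frontier(pts, degree = config$frontier$degree,
                              service = config$service))

  # --- normalization --------------------------------------------------
  pts <- stage("normalize", normalize_rates(pts, curve))
  summary_tab <- summarize_progress(pts$normalized, config$thresholds)
  say("normalized: %d rates, %d clamped", nrow(pts), sum(pts$clamped))

  results <- data.frame(country = rates$country, service = rates$service,
                        n_points = rates$n_points, rate = rates$rate,
                        rate_se = rates$rate_se, r_squared = rates$r_squared,
                        coverage_2000 = rates$coverage_2000,
                        normalized_rate = pts$normalized,
                        clamped = pts$clamped,
                        frontier_member = pts$is_frontier,
                        stringsAsFactors = FALSE)

  # --- associations ---------------------------------------------------
  models <- NULL
  if (isTRUE(config$run_associations) && !is.null(config$input$indicators)) {
    models <- stage("associate", {
      ind <- load_indicator_table(config$input$indicators)
      association_stage(results, ind, config$conflict_list)
    })
    say("associations: %d model(s) fitted", length(unique(models$model_id)))
  }

  out <- structure(list(config = config, points = pts, curve = curve,
                        results = results, summary = summary_tab,
                        models = models, log = log),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_outputs(out)
  invisible(out)
}

benchmark_outliers <- function(config) {
  man <- config$outliers$manual
  if (!length(man) && identical(config$input$rates, "benchmark"))
    man <- benchmark_frontier_sets(config$service)$outliers
  man
}

# PCA + Kaiser + (stepwise) linear and fractional-logit fits on all
# countries and on the no-conflict subset
association_stage <- function(results, indicators, conflict_list) {
  merged <- merge(results, as.data.frame(indicators), by = "country")
  rows <- list()
  subsets <- list(all = merged$country)
  if (length(conflict_list))
    subsets$no_conflict <- subset_no_conflict(merged$country, conflict_list)
  for (sub in names(subsets)) {
    d <- merged[merged$country %in% subsets[[sub]], , drop = FALSE]
    cc <- complete.cases(d[, WF_INDICATORS])
    if (sum(cc) < 12L) next
    pca <- run_pca(d[cc, c("country", WF_INDICATORS)])
    keep <- kaiser_retain(pca)
    scores <- as.data.frame(pca$scores[, keep, drop = FALSE])
    y <- d$normalized_rate[cc]
    lin <- backward_stepwise(y, scores, kind = "linear")
    rows[[paste0(sub, ".linear")]] <-
      model_rows(lin, paste0(sub, ".linear"), sub)
    pos <- y >= 0
    if (sum(pos) > ncol(scores) + 3L) {
      fl <- fit_fractional_logit(y[pos], scores[pos, , drop = FALSE])
      rows[[paste0(sub, ".fractional_logit")]] <-
        model_rows(fl, paste0(sub, ".fractional_logit"), sub)
    }
  }
  do.call(rbind, rows)
}

model_rows <- function(res, id, subset) {
  cbind(data.frame(model_id = id, model_kind = res$model_kind,
                   subset = subset, n = res$n,
                   overall_p = res$overall_p,
                   adj_r_squared = res$adj_r_squared,
                   stringsAsFactors = FALSE),
        res$coefficients)
}

write_pipeline_outputs <- function(out) {
  dir <- out$config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_results(out$results, file.path(dir, "results.csv"))
  write.csv(out$points, file.path(dir, "frontier_points.csv"), row.names = FALSE)
  cc <- coef(out$curve)
  write.csv(data.frame(degree = out$curve$degree,
                       coefficient = seq_along(cc), value = sprintf("%.17g", cc),
                       support = paste(out$curve$support$country, collapse = ";")),
            file.path(dir, "curve.csv"), row.names = FALSE)
  write.csv(out$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  if (!is.null(out$models))
    write.csv(out$models, file.path(dir, "models.csv"), row.names = FALSE)
  manifest <- list(config = unclass(out$config),
                   package_version = as.character(packageVersion("washfrontier")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   log = out$log)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run: %s, %d countries, frontier degree %d (%s)\n",
              x$config$service, nrow(x$results), x$curve$degree,
              x$config$frontier$method))
  cat("Frontier points:",
      paste(x$points$country[x$points$is_frontier], collapse = ", "), "\n")
  print(x$summary)
  invisible(x)
}
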