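# Relating normalized rates to socioeconomic indicators: PCA with Kaiser
# retention, linear and fractional-logit models, backward stepwise
# selection with re-entry, conflict subsetting and discordant pairs.

#' Principal component analysis of standardized indicators
#'
#' Correlation-matrix PCA: each indicator is z-standardized before the
#' decomposition, so the eigenvalues sum to the number of indicators and
#' the Kaiser rule (eigenvalue > 1) is meaningful. Rows with any missing
#' indicator are dropped (complete-case).
#'
#' @param x an `indicator_matrix` from [load_indicator_table()], or any
#'   data frame / matrix of numeric indicator columns (a `country` column
#'   is used for row labels if present).
#' @param columns which indicator columns to use; defaults to all numeric
#'   columns present.
#' @return Object of class `indicator_pca`: list with `eigenvalues`
#'   (non-increasing), `loadings` (variables x components), `scores`
#'   (complete-case rows x components), `n`, `countries`, `n_retained`
#'   (Kaiser count).
#' @export
run_pca <- function(x, columns = NULL) {
  df <- as.data.frame(x)
  countries <- df$country %||% rownames(df)
  num <- vapply(df, is.numeric, logical(1))
  cols <- columns %||% names(df)[num]
  m <- as.matrix(df[, cols, drop = FALSE])
  cc <- complete.cases(m)
  m <- m[cc, , drop = FALSE]
  if (nrow(m) <= ncol(m))
    stop_wf("need more complete-case rows (%d) than indicators (%d) for PCA",
            nrow(m), ncol(m), class = "wf_validation_error")
  if (nrow(m) < 10L)
    warning(sprintf("only %d complete-case rows; PCA will be unstable", nrow(m)))
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop_wf("constant indicator column(s) cannot be standardized: %s",
            paste(colnames(m)[sds == 0], collapse = ", "),
            class = "wf_degenerate_standardization_error")
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  structure(list(eigenvalues = ev,
                 loadings = pc$rotation,
                 scores = pc$x,
                 n = nrow(m),
                 countries = if (is.null(countries)) NULL else countries[cc],
                 n_retained = sum(ev > 1)),
            class = "indicator_pca")
}

#' @export
print.indicator_pca <- function(x, ...) {
  cat(sprintf("PCA of %d standardized indicators on %d complete cases\n",
              length(x$eigenvalues), x$n))
  cat("Eigenvalues:", paste(round(x$eigenvalues, 3), collapse = " "), "\n")
  cat(sprintf("Kaiser retention (eigenvalue > 1): %d component(s)\n", x$n_retained))
  invisible(x)
}

#' Kaiser criterion: retained component indices
#'
#' Components are retained iff their eigenvalue strictly exceeds 1 — under
#' standardization, iff they explain more variance than a single original
#' indicator.
#'
#' @param x an `indicator_pca`, or a numeric vector of eigenvalues.
#' @return integer vector of retained component indices (possibly empty).
#' @examples
#' kaiser_retain(c(4.395, 1.318, 1.089, 0.896, 0.597))
#' @export
kaiser_retain <- function(x) {
  ev <- if (inherits(x, "indicator_pca")) x$eigenvalues else as.numeric(x)
  which(ev > 1)
}

# --- regression results -------------------------------------------------

regression_result <- function(model_kind, fit, data, selected) {
  sm <- summary(fit)
  ct <- sm$coefficients
  if (model_kind == "linear") {
    ci <- suppressMessages(confint(fit))
    # confint drops to a vector for a single coefficient
    if (is.null(dim(ci))) ci <- matrix(ci, nrow = 1, dimnames = list(rownames(ct)))
    ci <- ci[rownames(ct), , drop = FALSE]
  } else {
    # Wald intervals: profile-likelihood CIs are not defined for the
    # quasi-likelihood fit and fail on degenerate responses
    z <- qnorm(0.975)
    ci <- cbind(ct[, 1] - z * ct[, 2], ct[, 1] + z * ct[, 2])
  }
  coefs <- data.frame(term = rownames(ct),
                      estimate = ct[, 1], se = ct[, 2],
                      ci_low = ci[, 1], ci_high = ci[, 2],
                      p_value = ct[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  if (model_kind == "linear") {
    fs <- sm$fstatistic
    overall_p <- if (is.null(fs)) NA_real_ else
      unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
    adj_r2 <- sm$adj.r.squared
  } else {
    overall_p <- wald_overall_p(fit)
    adj_r2 <- NA_real_
  }
  structure(list(model_kind = model_kind, coefficients = coefs,
                 n = nrow(data), overall_p = overall_p,
                 adj_r_squared = adj_r2,
                 selected_variables = selected, fit = fit),
            class = "regression_result")
}

# Wald chi-square test that all non-intercept coefficients are zero
wald_overall_p <- function(fit) {
  b <- coef(fit)
  keep <- names(b) != "(Intercept)"
  if (!any(keep)) return(NA_real_)
  b <- b[keep]
  V <- vcov(fit)[keep, keep, drop = FALSE]
  # a zero-dispersion (degenerate) fit has no usable covariance
  stat <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
  pchisq(stat, df = length(b), lower.tail = FALSE)
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s regression (n = %d)\n",
              if (x$model_kind == "linear") "Linear" else "Fractional-logit", x$n))
  print(transform(x$coefficients,
                  estimate = signif(estimate, 4), se = signif(se, 4),
                  ci_low = signif(ci_low, 4), ci_high = signif(ci_high, 4),
                  p_value = signif(p_value, 3)), row.names = FALSE)
  cat(sprintf("Overall %s p = %s",
              if (x$model_kind == "linear") "F-test" else "Wald",
              format.pval(x$overall_p, digits = 3)))
  if (!is.na(x$adj_r_squared))
    cat(sprintf(", adjusted R^2 = %.3f", x$adj_r_squared))
  cat("\n")
  invisible(x)
}

#' @export
coef.regression_result <- function(object, ...)
  setNames(object$coefficients$estimate, object$coefficients$term)

prepare_model_frame <- function(response, predictors, min_extra = 2L) {
  pred <- as.data.frame(predictors)
  stopifnot(length(response) == nrow(pred))
  dat <- cbind(data.frame(.response = response), pred)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < ncol(pred) + 1L + min_extra)
    stop_wf("too few complete cases (%d) for %d predictor(s)",
            nrow(dat), ncol(pred), class = "wf_validation_error")
  dat
}

#' Linear model of normalized rates on indicators
#'
#' Ordinary least squares of the normalized rate on the supplied
#' predictors (raw indicators or principal-component scores), with
#' complete-case deletion, 95% confidence intervals, adjusted R-squared
#' and the overall F-test.
#'
#' @param response numeric normalized rates.
#' @param predictors data frame or matrix of predictors.
#' @return a `regression_result`.
#' @export
fit_linear <- function(response, predictors) {
  dat <- prepare_model_frame(response, predictors)
  fit <- lm(.response ~ ., data = dat)
  if (anyNA(coef(fit)))
    stop_wf("collinear predictor(s): %s",
            paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
            class = "wf_rank_deficiency_error")
  regression_result("linear", fit, dat, setdiff(names(dat), ".response"))
}

#' Fractional-logit model of normalized rates on indicators
#'
#' Quasi-likelihood fit with a logit link on the mean of a fractional
#' response in \[0, 1\] (Papke-Wooldridge style). Responses exactly 0 or 1
#' — clamped frontier countries — are legitimate under quasi-likelihood
#' estimation, which is why this route is used instead of transforming the
#' response by the log-odds (undefined at the boundaries). Negative
#' normalized rates must be excluded by the caller before the fit: the
#' model is only defined for countries that made progress.
#'
#' @param response numeric normalized rates in \[0, 1\].
#' @param predictors data frame or matrix of predictors.
#' @return a `regression_result`; fitted means lie strictly in (0, 1).
#' @export
fit_fractional_logit <- function(response, predictors) {
  if (any(response < 0 | response > 1, na.rm = TRUE))
    stop_wf("fractional-logit response must lie in [0, 1]; exclude negative normalized rates first",
            class = "wf_exclusion_contract_error")
  dat <- prepare_model_frame(response, predictors)
  if (all(dat$.response == dat$.response[1]) &&
      dat$.response[1] %in% c(0, 1))
    stop_wf("all responses sit on the same boundary; the model is inestimable",
            class = "wf_inestimable_error")
  fit <- glm(.response ~ ., data = dat, family = quasibinomial("logit"))
  regression_result("fractional_logit", fit, dat,
                    setdiff(names(dat), ".response"))
}

#' Backward stepwise selection with re-entry
#'
#' Starts from the full model and repeatedly removes the predictor with
#' the largest p-value above `p_remove`; after every removal, any excluded
#' predictor whose p-value (when added back alone) falls below `p_enter`
#' re-enters. Terminates at a fixed point (no removal, no re-entry). The
#' re-entry reading is the only way an "addition" threshold is meaningful
#' inside a backward procedure.
#'
#' @param response numeric response vector.
#' @param predictors data frame or matrix of candidate predictors.
#' @param p_enter re-entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10).
#' @param kind `"linear"` or `"fractional_logit"`.
#' @param max_iter iteration cap; exceeding it raises a cycle error.
#' @return a `regression_result` for the selected model (intercept-only if
#'   everything is removed); `selected_variables` lists the surviving
#'   predictors.
#' @export
backward_stepwise <- function(response, predictors, p_enter = 0.05,
                              p_remove = 0.10,
                              kind = c("linear", "fractional_logit"),
                              max_iter = 50L) {
  kind <- match.arg(kind)
  pred <- as.data.frame(predictors)
  if (!ncol(pred))
    stop_wf("no candidate predictors", class = "wf_parameter_error")
  fit_fun <- if (kind == "linear") fit_linear else fit_fractional_logit
  fit_sub <- function(vars) {
    if (!length(vars)) {
      dat <- data.frame(.response = response)
      dat <- dat[complete.cases(dat), , drop = FALSE]
      f <- if (kind == "linear") lm(.response ~ 1, data = dat)
           else glm(.response ~ 1, data = dat, family = quasibinomial("logit"))
      return(regression_result(kind, f, dat, character(0)))
    }
    fit_fun(response, pred[, vars, drop = FALSE])
  }
  term_p <- function(res) {
    cf <- res$coefficients
    setNames(cf$p_value, cf$term)[setdiff(cf$term, "(Intercept)")]
  }
  current <- names(pred)
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    res <- fit_sub(current)
    p <- term_p(res)
    if (length(p) && max(p) > p_remove) {
      current <- setdiff(current, names(p)[which.max(p)])
      changed <- TRUE
      # re-entry pass: test each excluded variable against the new model
      repeat {
        readd <- NULL
        best <- p_enter
        for (v in setdiff(names(pred), current)) {
          pv <- term_p(fit_sub(c(current, v)))[v]
          if (!is.na(pv) && pv < best) { best <- pv; readd <- v }
        }
        if (is.null(readd)) break
        current <- c(current, readd)
      }
    }
    if (!changed) return(fit_sub(current))
  }
  stop_wf("stepwise selection did not reach a fixed point in %d iterations",
          max_iter, class = "wf_stepwise_cycle_error")
}

#' Drop countries affected by armed conflict
#'
#' Order-preserving set difference; conflict-list entries that do not
#' occur in the data are ignored with a warning.
#'
#' @param countries character vector of study countries.
#' @param conflict_list character vector of countries with armed conflict
#'   during the study period (user-supplied).
#' @return `countries` without the conflict entries.
#' @export
subset_no_conflict <- function(countries, conflict_list) {
  unused <- setdiff(conflict_list, countries)
  if (length(unused))
    warning(sprintf("conflict-list entr%s not present in the data: %s",
                    if (length(unused) == 1) "y" else "ies",
                    paste(unused, collapse = ", ")))
  countries[!countries %in% conflict_list]
}

#' Side-by-side comparison of a discordant country pair
#'
#' @param country_a,country_b identifiers present in both tables.
#' @param indicators an indicator table (data frame with a `country`
#'   column; extra non-indicator columns are carried along).
#' @param rates data frame with columns `country` and `normalized`
#'   (e.g. from [normalize_rates()]), and optionally `coverage`.
#' @return data frame with one row per compared field: `field`,
#'   `value_a`, `value_b`, `difference` (a minus b).
#' @export
compare_pair <- function(country_a, country_b, indicators, rates) {
  ind <- as.data.frame(indicators)
  grab <- function(df, ctry, what) {
    i <- which(df$country == ctry)
    if (!length(i))
      stop_wf("country %s not found in the %s table", ctry, what,
              class = "wf_lookup_error")
    df[i[1], , drop = FALSE]
  }
  ra <- grab(rates, country_a, "normalized-rate")
  rb <- grab(rates, country_b, "normalized-rate")
  ia <- grab(ind, country_a, "indicator")
  ib <- grab(ind, country_b, "indicator")
  fields <- c("normalized_rate",
              if ("coverage" %in% names(rates)) "initial_coverage",
              setdiff(names(ind)[vapply(ind, is.numeric, logical(1))], "country"))
  va <- c(ra$normalized,
          if ("coverage" %in% names(rates)) ra$coverage,
          unlist(ia[setdiff(fields, c("normalized_rate", "initial_coverage"))]))
  vb <- c(rb$normalized,
          if ("coverage" %in% names(rates)) rb$coverage,
          unlist(ib[setdiff(fields, c("normalized_rate", "initial_coverage"))]))
  out <- data.frame(field = fields, value_a = unname(va), value_b = unname(vb))
  out <- out[!(is.na(out$value_a) & is.na(out$value_b)), , drop = FALSE]
  rownames(out) <- NULL
  out$difference <- out$value_a - out$value_b
  attr(out, "countries") <- c(country_a, country_b)
  out
}
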