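test_that("correlation-matrix PCA recovers closed-form bivariate eigenvalues", {
  set.seed(501)
  n <- 20000
  rho <- 0.6
  x1 <- rnorm(n)
  x2 <- rho * x1 + sqrt(1 - rho^2) * rnorm(n)
  pca <- run_pca(data.frame(a = x1, b = x2))
  expect_equal(pca$eigenvalues, c(1 + rho, 1 - rho), tolerance = 0.02)

  indep <- run_pca(as.data.frame(matrix(rnorm(n * 4), n, 4)))
  expect_equal(indep$eigenvalues, rep(1, 4), tolerance = 0.05)
})

test_that("PCA invariants: ordering, total variance, orthogonal scores", {
  set.seed(502)
  m <- as.data.frame(matrix(rnorm(60 * 5), 60, 5) %*%
                       matrix(runif(25, -1, 1), 5, 5))
  pca <- run_pca(m)
  expect_true(all(diff(pca$eigenvalues) <= 0))
  expect_equal(sum(pca$eigenvalues), 5, tolerance = 1e-6)
  cors <- cor(pca$scores)
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-8)
  m$flat <- 1
  expect_error(run_pca(m), class = "wf_degenerate_standardization_error")
})

test_that("Kaiser retention keeps components with eigenvalue strictly above 1", {
  printed <- c(4.395, 1.318, 1.089, 0.896, 0.597, 0.391, 0.194, 0.091, 0.029)
  expect_identical(kaiser_retain(printed), 1:3)
  expect_length(kaiser_retain(rep(1, 5)), 0)
  expect_identical(kaiser_retain(c(2, 1.5, 0.9)), 1:2)
})

test_that("the linear model reproduces exact relationships and names collinearity", {
  x <- seq(0, 1, length.out = 20)
  # an exact relationship makes summary.lm grumble; that is the point here
  res <- suppressWarnings(fit_linear(0.2 + 0.5 * x, data.frame(x = x)))
  cf <- res$coefficients
  expect_equal(cf$estimate[cf$term == "x"], 0.5, tolerance = 1e-10)
  expect_lt(cf$ci_high[2] - cf$ci_low[2], 1e-8)
  expect_error(fit_linear(rnorm(20), data.frame(x = x, y = 2 * x)),
               class = "wf_rank_deficiency_error")
})

test_that("linear coefficients are recovered within 3 standard errors", {
  set.seed(503)
  n <- 80
  x <- runif(n, 0, 50)
  y <- 0.1 + 0.01 * x + rnorm(n, sd = 0.15)
  res <- fit_linear(y, data.frame(x = x))
  cf <- res$coefficients[res$coefficients$term == "x", ]
  expect_lt(abs(cf$estimate - 0.01), 3 * cf$se)
})

test_that("fractional logit handles boundaries, rejects negatives, recovers parameters", {
  x <- seq(-2, 2, length.out = 30)
  flat <- fit_fractional_logit(rep(0.5, 30), data.frame(x = x))
  expect_equal(coef(flat)[["(Intercept)"]], 0, tolerance = 1e-8)
  expect_equal(coef(flat)[["x"]], 0, tolerance = 1e-8)

  expect_error(fit_fractional_logit(c(-0.2, 0.5, 0.7), data.frame(x = 1:3)),
               class = "wf_exclusion_contract_error")
  expect_error(fit_fractional_logit(rep(1, 10), data.frame(x = 1:10)),
               class = "wf_inestimable_error")

  set.seed(504)
  n <- 200
  xr <- rnorm(n)
  b0 <- -0.3; b1 <- 0.8
  mu <- plogis(b0 + b1 * xr)
  phi <- 30   # beta-distributed fractional response around the logit mean
  y <- rbeta(n, mu * phi, (1 - mu) * phi)
  res <- fit_fractional_logit(y, data.frame(x = xr))
  cf <- res$coefficients[res$coefficients$term == "x", ]
  expect_lt(abs(cf$estimate - b1), 3 * cf$se)
  expect_true(all(fitted(res$fit) > 0 & fitted(res$fit) < 1))
  # clamped frontier countries (exact 1) are legitimate inputs
  res1 <- fit_fractional_logit(c(y[1:50], 1, 1), data.frame(x = c(xr[1:50], 1, 2)))
  expect_s3_class(res1, "regression_result")
})

test_that("backward stepwise removes noise, keeps signal, and refits consistently", {
  set.seed(505)
  n <- 100
  strong <- rnorm(n)
  noise <- rnorm(n)
  y <- 0.5 * strong + rnorm(n, sd = 0.3)
  sel <- backward_stepwise(y, data.frame(strong = strong, noise = noise))
  expect_identical(sel$selected_variables, "strong")
  # the reported model equals a standalone refit of the selected variables
  refit <- fit_linear(y, data.frame(strong = strong))
  expect_equal(coef(sel), coef(refit))
  # a single weak predictor is dropped to the intercept-only model
  set.seed(506)
  weak <- rnorm(50)
  yw <- rnorm(50)
  p_weak <- fit_linear(yw, data.frame(weak = weak))$coefficients$p_value[2]
  if (p_weak > 0.10) {
    drop_all <- backward_stepwise(yw, data.frame(weak = weak))
    expect_length(drop_all$selected_variables, 0)
  }
  expect_true(all(sel$selected_variables %in% c("strong", "noise")))
})

test_that("null predictors are discarded in most replicates", {
  set.seed(507)
  reps <- 100
  kept <- replicate(reps, {
    y <- rnorm(60)
    x <- as.data.frame(matrix(rnorm(60 * 3), 60, 3))
    length(backward_stepwise(y, x)$selected_variables) > 0
  })
  # each null predictor is retained when its final p <= .10, so the
  # expected non-empty rate is about 1 - 0.9^3 = 0.27
  expect_lt(mean(kept), 0.45)
  expect_gt(mean(kept), 0.05)
})

test_that("conflict subsetting is an order-preserving set difference", {
  countries <- c("KEN", "UGA", "TZA", "RWA")
  expect_identical(subset_no_conflict(countries, character(0)), countries)
  expect_identical(subset_no_conflict(countries, c("UGA", "RWA")), c("KEN", "TZA"))
  expect_warning(out <- subset_no_conflict(countries, "XXX"), "not present")
  expect_identical(out, countries)
})

test_that("discordant pairs reproduce the packaged comparisons", {
  ind <- load_indicator_table(system.file("extdata", "indicators_pairs.csv",
                                          package = "washfrontier"))
  pairs_w <- load_pairings("water")
  rates_w <- data.frame(country = pairs_w$iso3,
                        normalized = pairs_w$normalized_rate,
                        coverage = pairs_w$initial_coverage)
  cmp <- compare_pair("EGY", "JOR", ind, rates_w)
  expect_equal(cmp$value_a[cmp$field == "normalized_rate"], 0.23)
  expect_equal(cmp$value_b[cmp$field == "normalized_rate"], -0.38)
  expect_equal(cmp$difference[cmp$field == "normalized_rate"], 0.61)

  pairs_s <- load_pairings("sanitation")
  rates_s <- data.frame(country = pairs_s$iso3,
                        normalized = pairs_s$normalized_rate,
                        coverage = pairs_s$initial_coverage)
  cmp2 <- compare_pair("KEN", "RWA", ind, rates_s)
  expect_equal(cmp2$value_a[cmp2$field == "normalized_rate"], 0.20)
  expect_equal(cmp2$value_b[cmp2$field == "normalized_rate"], 1.0)

  self <- compare_pair("KEN", "KEN", ind, rates_s)
  expect_true(all(self$difference == 0))
  expect_error(compare_pair("KEN", "ZZZ", ind, rates_s), class = "wf_lookup_error")
})
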