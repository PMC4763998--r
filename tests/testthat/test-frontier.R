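test_that("upper convex hull identification matches a brute-force oracle", {
  set.seed(301)
  for (trial in 1:300) {
    n <- sample(1:12, 1)
    pts <- performance_points(sprintf("C%02d", seq_len(n)),
                              runif(n, 5, 99), runif(n, 0.05, 3.5))
    got <- identify_frontier_points(pts)
    expect_identical(which(got$is_frontier), bf_upper_hull(pts$coverage, pts$rate),
                     info = paste("trial", trial))
  }
})

test_that("a single candidate is its own frontier", {
  pts <- identify_frontier_points(performance_points("A", 50, 2.0))
  expect_true(pts$is_frontier)
})

test_that("non-positive rates and outliers are never frontier candidates", {
  pts <- performance_points(c("UP", "FLAT", "DOWN", "OUT"),
                            c(40, 60, 80, 50), c(1.5, 0, -0.5, 3.5))
  pts <- flag_outliers(pts, alpha = NULL, manual_list = "OUT")
  got <- identify_frontier_points(pts)
  expect_identical(hull_countries(got), "UP")
  expect_error(identify_frontier_points(
    performance_points("A", 50, -1)), class = "wf_no_frontier_error")
})

test_that("pareto dominance and explicit-list methods behave as specified", {
  pts <- performance_points(c("A", "B", "C", "D"),
                            c(30, 50, 50, 70), c(2, 2.5, 1, 1.5))
  par <- identify_frontier_points(pts, method = "pareto_dominance")
  # C and D are dominated: A (and B) reach strictly higher rates from
  # lower-or-equal coverage; A and B are undominated
  expect_identical(hull_countries(par), c("A", "B"))
  exp <- identify_frontier_points(pts, method = "explicit_list",
                                  explicit = c("C", "D"))
  expect_identical(hull_countries(exp), c("C", "D"))
  expect_error(identify_frontier_points(pts, method = "explicit_list"),
               class = "wf_parameter_error")
})

test_that("one-sided Grubbs screening matches the direct formula", {
  pts <- performance_points(sprintf("G%d", 1:4), c(30, 40, 50, 60),
                            c(2.0, 2.1, 2.2, 6.0))
  flagged <- flag_outliers(pts, alpha = 0.05)
  # independent computation of the statistic and critical value
  r <- c(2.0, 2.1, 2.2, 6.0)
  G <- (max(r) - mean(r)) / sd(r)
  t <- qt(1 - 0.05 / 4, 2)
  crit <- (3 / sqrt(4)) * sqrt(t^2 / (2 + t^2))
  expect_identical(flagged$is_outlier, r == 6.0 & G > crit)
  expect_identical(flagged$outlier_method[4], "grubbs")

  same <- flag_outliers(performance_points(letters[1:4], c(30, 40, 50, 60),
                                           rep(2, 4)), alpha = 0.05)
  expect_false(any(same$is_outlier))   # zero spread flags nothing

  manual <- flag_outliers(pts, alpha = NULL, manual_list = "G2")
  expect_identical(manual$country[manual$is_outlier], "G2")
  expect_identical(manual$outlier_method[2], "manual")
  expect_error(flag_outliers(pts, alpha = 1.5), class = "wf_parameter_error")
})

test_that("the fitted curve interpolates a single point and passes through (100, 0)", {
  pts <- performance_points("A", 50, 2.0)
  pts$is_frontier <- TRUE
  fc <- fit_frontier(pts, degree = 1)
  expect_equal(max_rate(fc, 75), 1.0)
  expect_equal(max_rate(fc, 0), 4.0)
  expect_identical(max_rate(fc, 100), 0)
})

test_that("constrained least squares matches brute-force normal equations", {
  bench <- frontier_benchmark("water")
  fp <- bench$points[bench$points$is_frontier, ]
  fc2 <- fit_frontier(fp, degree = 2, use_all = TRUE)
  u <- 100 - fp$coverage
  X <- cbind(u, u^2)
  beta <- solve(t(X) %*% X, t(X) %*% fp$rate)   # independent oracle
  expect_equal(unname(coef(fc2)), unname(drop(beta)), tolerance = 1e-10)
})

test_that("every fitted curve is zero at full coverage and non-negative after clipping", {
  set.seed(302)
  for (trial in 1:25) {
    n <- sample(3:9, 1)
    pts <- performance_points(seq_len(n), runif(n, 10, 95), runif(n, 0.1, 3))
    pts$is_frontier <- TRUE
    fc <- fit_frontier(pts, degree = sample(1:3, 1))
    expect_identical(max_rate(fc, 100), 0)
    expect_true(all(max_rate(fc, seq(0, 100, by = 0.25)) >= 0))
  }
  expect_error(fit_frontier(data.frame(country = "A", coverage = 50, rate = 2,
                                       is_frontier = TRUE), degree = 3),
               class = "wf_underdetermined_fit_error")
  expect_error(max_rate(frontier_curve(0.02), 101), class = "wf_domain_error")
})

test_that("benchmark water curve reproduces the published frontier behaviour", {
  bench <- frontier_benchmark("water")
  expect_identical(hull_countries(bench$points), water_frontier_countries)
  # implied maxima decrease with coverage at the near-universal end,
  # matching the printed Jordan (96.7) / Albania (97.1) / Egypt (97.3) order
  mr <- max_rate(bench$curve, c(96.7, 97.1, 97.3))
  expect_true(all(diff(mr) < 0))
  # non-negative over the observed coverage range
  expect_true(all(max_rate(bench$curve, seq(26.2, 100, by = 0.1)) >= 0))
})
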