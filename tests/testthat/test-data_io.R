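test_that("coverage CSV loading enforces the year-2000 floor and keeps duplicate years", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country,service,year,coverage",
               "KEN,water,1999,48",
               "KEN,water,2000,50", "KEN,water,2002,52",
               "KEN,water,2004,53", "KEN,water,2004,55",
               "KEN,water,2006,56",
               "UGA,sanitation,2001,30"), path)
  expect_warning(series <- load_coverage_series(path), "before year 2000")
  expect_named(series, c("KEN.water", "UGA.sanitation"))
  ken <- series$KEN.water
  expect_equal(nrow(ken), 5)                 # 1999 row dropped
  expect_equal(sum(ken$year == 2004), 2)     # duplicates kept independently

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country,year,coverage", "KEN,2000,50"), bad)
  expect_error(load_coverage_series(bad), "missing column",
               class = "wf_format_error")
  oob <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country,service,year,coverage", "KEN,water,2000,101"), oob)
  expect_error(load_coverage_series(oob), "row 1",
               class = "wf_validation_error")
})

test_that("series constructor rejects invalid observations", {
  expect_error(coverage_series("A", "water", 1999, 50), "before 2000",
               class = "wf_validation_error")
  expect_error(coverage_series("A", "water", 2000, -1), class = "wf_validation_error")
  expect_error(coverage_series("A", "water", integer(0), numeric(0)),
               class = "wf_validation_error")
})

test_that("inclusion filter needs five points over three distinct years", {
  ok <- apply_inclusion_filter(make_series(2000:2004, rep(50, 5)))
  expect_true(ok$included)
  expect_identical(ok$reason, "")

  few_years <- apply_inclusion_filter(
    make_series(c(2000, 2000, 2000, 2001, 2001, 2001), rep(50, 6)))
  expect_false(few_years$included)
  expect_match(few_years$reason, "distinct years")

  few_points <- apply_inclusion_filter(make_series(2000:2003, rep(50, 4)))
  expect_false(few_points$included)
  expect_match(few_points$reason, "5 points")
})

test_that("inclusion is monotone: a survey in a new year never drops a country", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(3:8, 1)
    yrs <- sample(2000:2010, n, replace = TRUE)
    s <- make_series(yrs, runif(n, 20, 80))
    before <- apply_inclusion_filter(s)$included
    new_year <- setdiff(2000:2012, yrs)[1]
    s2 <- make_series(c(yrs, new_year), c(s$coverage, 50))
    after <- apply_inclusion_filter(s2)$included
    expect_false(before && !after)
  }
})

test_that("packaged progress table has the published block sizes", {
  tab <- load_progress_table()
  expect_equal(nrow(tab), 73)
  water <- progress_table_service(tab, "water")
  san <- progress_table_service(tab, "sanitation")
  expect_equal(nrow(water), 67)
  expect_equal(nrow(san), 61)
  expect_true(all(abs(water$normalized) <= 1))
  expect_true(all(abs(san$normalized) <= 1))
  # the printed "-0.00" rate (negative, rounded to zero) must read as
  # non-positive so it can never be a frontier candidate
  expect_false(water$rate[water$iso3 == "JAM"] > 0)
})

test_that("indicator table handles known, unknown and absent columns", {
  path <- system.file("extdata", "indicators_pairs.csv", package = "washfrontier")
  ind <- load_indicator_table(path)
  expect_equal(nrow(ind), 12)
  avail <- attr(ind, "available")
  expect_equal(sum(colSums(avail) == 12), 5)   # five indicators populated
  expect_equal(sum(colSums(avail) == 0), 4)    # the other four absent

  odd <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country,gini,shoe_size", "KEN,42.5,43"), odd)
  expect_warning(ind2 <- load_indicator_table(odd), "shoe_size")
  expect_false("shoe_size" %in% names(ind2))
  expect_equal(ind2$gini, 42.5)

  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_equal(nrow(load_indicator_table(empty)), 0)

  oob <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country,hdi", "KEN,1.2"), oob)
  expect_error(load_indicator_table(oob), class = "wf_validation_error")
})

test_that("results survive a write/load round trip bit-identically", {
  res <- data.frame(country = c("KEN", "UGA"), service = "water",
                    n_points = c(7L, 10L),
                    rate = c(0.7, 1 / 3), rate_se = c(0.1, sqrt(2)),
                    r_squared = c(0.27, exp(-1)),
                    coverage_2000 = c(52.9, 56.8),
                    normalized_rate = c(0.2847519283746571, 2 / 3),
                    clamped = c(FALSE, TRUE), frontier_member = c(FALSE, FALSE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(res, path)
  back <- load_results(path)
  for (col in names(res)) expect_identical(back[[col]], unname(unlist(res[[col]])))
})
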