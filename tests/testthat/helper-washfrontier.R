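# shared builders and independent oracles

make_series <- function(years, coverage, country = "XXX", service = "water") {
  coverage_series(country, service, years, coverage)
}

# independent O(n^3) upper-hull oracle: a point (in general position) is a
# vertex iff no pair of other points spans it from above or at its height
bf_upper_hull <- function(x, y) {
  n <- length(x)
  if (n == 1L) return(1L)
  vertex <- logical(n)
  for (k in seq_len(n)) {
    covered <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == k || j == k || x[i] >= x[j]) next
        if (x[i] <= x[k] && x[k] <= x[j]) {
          yline <- y[i] + (y[j] - y[i]) * (x[k] - x[i]) / (x[j] - x[i])
          if (y[k] <= yline) { covered <- TRUE; break }
        }
      }
      if (covered) break
    }
    vertex[k] <- !covered
  }
  which(vertex)
}

hull_countries <- function(points) {
  sort(points$country[points$is_frontier])
}

# closed-form simple-regression slope from raw sums
sums_slope <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

water_frontier_countries <- c("ARM", "EGY", "ETH", "GHA", "WSM")
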