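cell_tbl <- function(s, e, q, country = NULL, unit1 = NULL) {
  out <- tibble::tibble(survival_bar = s, education_bar = e, wealth_bar = q)
  out$country <- if (is.null(country)) sprintf("C%02d", seq_along(s)) else country
  if (!is.null(unit1)) out$unit1 <- unit1
  out
}

test_that("observed extrema over the reference table match the printed range", {
  t1 <- load_fixture("table1")
  cells <- tibble::tibble(education_bar = t1$maternal_schooling_years)
  b <- compute_bounds(cells, "Edu", "across_countries", "observed_extrema")
  expect_equal(c(b$lower, b$upper), c(0.7, 12.1))
})

test_that("fixed goalposts echo their input and default to natural bounds", {
  b <- compute_bounds(component = "Edu", mode = "fixed_goalposts",
                      goalposts = c(0, 15))
  expect_equal(c(b$lower, b$upper), c(0, 15))
  expect_equal(default_goalposts(),
               list(U5S = c(0, 1), Edu = c(0, 15), Wealth = c(1, 5)))
})

test_that("observed bounds equal a brute-force scan on random cell tables", {
  set.seed(51)
  for (i in 1:20) {
    cells <- cell_tbl(runif(12), runif(12, 0, 14), runif(12, 1, 5))
    for (cmp in c("U5S", "Edu", "Wealth")) {
      col <- switch(cmp, U5S = "survival_bar", Edu = "education_bar",
                    Wealth = "wealth_bar")
      b <- compute_bounds(cells, cmp, mode = "observed_extrema")
      lo <- Inf; hi <- -Inf
      for (v in cells[[col]]) { lo <- min(lo, v); hi <- max(hi, v) }
      expect_equal(c(b$lower, b$upper), c(lo, hi), tolerance = 1e-12)
    }
  }
})

test_that("degenerate extrema instruct switching to fixed goalposts", {
  cells <- cell_tbl(c(0.9, 0.9), c(3, 3), c(2, 2))
  expect_error(compute_bounds(cells, "Edu", mode = "observed_extrema"),
               "fixed goalposts")
  expect_error(compute_bounds(cells[1L, ], "Edu", mode = "observed_extrema"),
               ">= 2 cells")
})

test_that("normalization maps bounds to 0 and 1 and is affine-invariant", {
  b <- compute_bounds(component = "Edu", mode = "fixed_goalposts",
                      goalposts = c(0.7, 12.1))
  expect_equal(normalize_indicator(0.7, b), 0)
  expect_equal(normalize_indicator(12.1, b), 1)
  # global-average schooling against the observed national extrema
  expect_equal(normalize_indicator(5.6, b), (5.6 - 0.7) / (12.1 - 0.7))
  expect_equal(normalize_indicator(5.6, b), 0.4298246, tolerance = 1e-6)
  # rescaling values and bounds by a + b x leaves the output unchanged
  b2 <- compute_bounds(component = "Edu", mode = "fixed_goalposts",
                       goalposts = 2 + 3 * c(0.7, 12.1))
  expect_equal(normalize_indicator(2 + 3 * 5.6, b2),
               normalize_indicator(5.6, b), tolerance = 1e-12)
})

test_that("out-of-range values clamp with warning or error per the clamp flag", {
  b <- compute_bounds(component = "Wealth", mode = "fixed_goalposts")
  expect_warning(z <- normalize_indicator(c(0.5, 3), b), "clamped")
  expect_equal(z, c(0, 0.5))
  expect_error(normalize_indicator(0.5, b, clamp = FALSE), "outside")
})

test_that("the two mean types agree with closed forms", {
  expect_equal(compute_index(1, 1, 1, "geometric"), 1)
  expect_equal(compute_index(1, 1, 1, "arithmetic"), 1)
  expect_equal(compute_index(0, 0.9, 0.9, "geometric"), 0)
  expect_equal(compute_index(0, 0.9, 0.9, "arithmetic"), 0.6)
  expect_equal(compute_index(0.25, 0.5, 1.0, "geometric"), 0.5)
  expect_error(compute_index(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("geometric never exceeds arithmetic, equal iff components equal", {
  set.seed(52)
  for (i in 1:200) {
    v <- runif(3)
    g <- compute_index(v[1], v[2], v[3], "geometric")
    a <- compute_index(v[1], v[2], v[3], "arithmetic")
    expect_lte(g, a + 1e-12)
    if (diff(range(v)) > 1e-6) expect_lt(g, a)
  }
  v <- runif(1)
  expect_equal(compute_index(v, v, v, "geometric"),
               compute_index(v, v, v, "arithmetic"), tolerance = 1e-12)
})

test_that("the index is monotone non-decreasing in each component", {
  set.seed(53)
  for (i in 1:50) {
    v <- runif(3, 0.05, 0.9)
    for (j in 1:3) {
      hi <- v; hi[j] <- hi[j] + 0.05
      expect_gte(compute_index(hi[1], hi[2], hi[3], "geometric"),
                 compute_index(v[1], v[2], v[3], "geometric"))
    }
  }
})

test_that("national ranking equals a sort oracle with alphabetical ties", {
  set.seed(54)
  cells <- cell_tbl(runif(10, 0.85, 0.99), runif(10, 1, 12), runif(10, 1.5, 4.5))
  tab <- build_index_table(cells)
  ord <- order(-tab$index)
  expect_equal(tab$rank, seq_len(10L))
  expect_equal(tab$index, sort(tab$index, decreasing = TRUE))
  # tie case: two countries engineered identical
  cells2 <- cells
  cells2[2L, c("survival_bar", "education_bar", "wealth_bar")] <-
    cells2[1L, c("survival_bar", "education_bar", "wealth_bar")]
  tab2 <- build_index_table(cells2)
  tied <- tab2$country[tab2$index == tab2$index[tab2$country == cells2$country[1L]]]
  expect_equal(tied, sort(tied))
})

test_that("observed-extrema normalization sends the extreme country to zero", {
  cells <- cell_tbl(c(0.99, 0.95, 0.90), c(12, 6, 1), c(4, 3, 2))
  bounds <- lapply(stats::setNames(nm = c("U5S", "Edu", "Wealth")), function(cmp)
    compute_bounds(cells, cmp, "across_countries", "observed_extrema"))
  tab <- build_index_table(cells, bounds)
  expect_equal(min(tab$index), 0)
  expect_equal(tab$index[tab$country == "C03"], 0)
})

test_that("within-country statistics match closed forms and a loop oracle", {
  st <- within_country_stats(c(0.4, 0.6))
  expect_equal(st$mean, 0.5)
  expect_equal(st$sd, sqrt(0.02), tolerance = 1e-7)
  expect_equal(within_country_stats(rep(0.3, 5L))$sd, 0)
  set.seed(55)
  v <- runif(12)
  st2 <- within_country_stats(v)
  expect_equal(st2$sd, oracle_sample_sd(v), tolerance = 1e-12)
  expect_equal(st2$mean, sum(v) / 12, tolerance = 1e-12)
  one <- within_country_stats(0.5)
  expect_true(is.na(one$sd))
  expect_false(one$sd_defined)
})

test_that("unit tables carry per-country dispersion; single units are flagged", {
  cells <- cell_tbl(c(0.9, 0.95, 0.99), c(3, 6, 9), c(2, 3, 4),
                    country = c("AA", "AA", "BB"),
                    unit1 = c("U1", "U2", "U1"))
  tab <- build_index_table(cells)
  smry <- within_country_summary(tab)
  expect_equal(smry$country, c("AA", "BB"))
  expect_false(smry$sd_defined[smry$country == "BB"])
  aa <- tab$index[tab$country == "AA"]
  expect_equal(smry$within_mean[1L], mean(aa))
  expect_equal(smry$within_sd[1L], sd(aa))
})

test_that("mismatched bound scopes are refused", {
  cells <- cell_tbl(c(0.9, 0.95), c(3, 6), c(2, 3))
  bounds <- list(
    U5S = compute_bounds(component = "U5S", scope = "across_countries",
                         mode = "fixed_goalposts"),
    Edu = compute_bounds(component = "Edu", scope = "within_country_units",
                         mode = "fixed_goalposts"),
    Wealth = compute_bounds(component = "Wealth", scope = "across_countries",
                            mode = "fixed_goalposts"))
  expect_error(build_index_table(cells, bounds), "scope mismatch")
})
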