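test_that("pearson correlation matches closed cases and a formula oracle", {
  v <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_correlation(v, v)$r, 1)
  expect_equal(pearson_correlation(v, 2 * mean(v) - v)$r, -1)
  set.seed(61)
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(pearson_correlation(x, y)$r, oracle_pearson(x, y),
                 tolerance = 1e-12)
  }
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_correlation(1:2, 2:3), "3 pairs")
})

test_that("correlation is invariant under positive affine transforms", {
  set.seed(62)
  x <- rnorm(20); y <- x + rnorm(20)
  r0 <- pearson_correlation(x, y)$r
  expect_equal(pearson_correlation(2 + 3 * x, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, 0.5 * y - 1)$r, r0, tolerance = 1e-12)
})

test_that("external index comparison reports matched and unmatched countries", {
  idx <- tibble::tibble(country = c("AA", "BB", "CC", "DD"),
                        index = c(0.2, 0.4, 0.6, 0.8))
  ext <- tibble::tibble(country = c("AA", "BB", "CC", "EE"),
                        hdi = c(0.3, 0.5, 0.7, 0.9))
  got <- compare_indices(idx, ext)
  expect_equal(got$n_pairs, 3L)
  expect_equal(got$r, 1)
  expect_setequal(got$unmatched, c("DD", "EE"))
})

test_that("identical rounds give zero deltas; extra units are reported", {
  cells <- tibble::tibble(country = "AA", unit1 = c("U1", "U2", "U3"),
                          survival_bar = c(0.9, 0.92, 0.95),
                          index = c(0.4, 0.5, 0.6))
  same <- round_change(cells, cells)
  expect_true(all(abs(same$deltas$delta_index) < 1e-15))
  expect_equal(nrow(same$unmatched), 0L)
  t1 <- dplyr::bind_rows(cells[-1L, ],
                         tibble::tibble(country = "AA", unit1 = "U9",
                                        survival_bar = 0.8, index = 0.3))
  got <- round_change(cells, t1)
  expect_setequal(got$unmatched$unit1, c("U1", "U9"))
  expect_error(round_change(cells, cells[0L, ]), "zero matched")
})

test_that("a mortality-declining second round shows positive survival deltas", {
  survey <- generate_survey(generator_config(
    n_countries = 2L, units_per_country = 3L, clusters_per_unit = 12L,
    households_per_cluster = 12L, u5m_range = c(0.08, 0.15),
    two_rounds = TRUE, u5m_trend = 0.8, seed = 63L))
  recs <- filter_birth_window(survey$records, "years_10")
  recs$wealth_quintile <- 3L
  rounds <- split(recs, recs$survey_year)
  cells <- lapply(rounds, aggregate_components, level = "unit1")
  got <- round_change(cells[["2005"]], cells[["2015"]])
  expect_gt(median(got$deltas$delta_survival_bar), 0)
})

test_that("thin-plate interpolation reproduces its source points exactly", {
  set.seed(64)
  pts <- data.frame(x = runif(20), y = runif(20), z = runif(20, 0.5, 1))
  grid <- build_contour_grid(pts, resolution = 12L)
  expect_s3_class(grid, "contour_grid")
  zhat <- evaluate_contour(grid, pts$x, pts$y)
  expect_lt(max(abs(zhat - pts$z)), 1e-8)
  # resolution refinement does not change the interpolant
  grid2 <- build_contour_grid(pts, resolution = 24L)
  expect_lt(max(abs(evaluate_contour(grid2, pts$x, pts$y) - pts$z)), 1e-8)
  expect_equal(length(grid$levels), 11L)
  expect_true(all(grid$z >= min(pts$z) - 1e-12 & grid$z <= max(pts$z) + 1e-12))
})

test_that("thin-plate values agree with a direct radial-basis solve oracle", {
  set.seed(65)
  pts <- data.frame(x = runif(15), y = runif(15), z = rnorm(15))
  grid <- build_contour_grid(pts, resolution = 8L)
  qx <- runif(10); qy <- runif(10)
  expect_equal(evaluate_contour(grid, qx, qy),
               oracle_tps_eval(pts$x, pts$y, pts$z, qx, qy),
               tolerance = 1e-8)
})

test_that("three points defining a plane reproduce the plane in linear mode", {
  pts <- data.frame(x = c(0, 1, 0), y = c(0, 0, 1), z = c(1, 3, 2))
  grid <- build_contour_grid(pts, resolution = 5L, interpolation = "linear")
  plane <- function(x, y) 1 + 2 * x + 1 * y
  got <- evaluate_contour(grid, c(0.2, 0.5), c(0.3, 0.25))
  expect_equal(got, plane(c(0.2, 0.5), c(0.3, 0.25)), tolerance = 1e-10)
})

test_that("collinear points fall back to linear interpolation with a warning", {
  pts <- data.frame(x = c(0, 0.5, 1), y = c(0, 0.5, 1), z = c(0, 1, 2))
  expect_warning(grid <- build_contour_grid(pts, resolution = 5L), "collinear")
  expect_equal(grid$method, "linear")
})

test_that("contour plotting returns a ggplot object", {
  set.seed(66)
  pts <- data.frame(x = runif(8), y = runif(8), z = runif(8))
  p <- plot_contour(build_contour_grid(pts, resolution = 10L))
  expect_s3_class(p, "ggplot")
})

test_that("decile bins are equal-count with deterministic tie-breaks", {
  v20 <- seq(0.1, 0.9, length.out = 20L)
  d <- decile_bins(v20, sprintf("u%02d", 1:20))
  expect_equal(unname(table(d)), rep(2L, 10L), ignore_attr = TRUE)
  # Philippines-like: 17 units, sizes differ by at most one
  d17 <- decile_bins(runif(17), sprintf("u%02d", 1:17))
  expect_lte(diff(range(table(d17))), 1L)
  # ties broken by name
  d_tie <- decile_bins(rep(0.5, 20L), sprintf("u%02d", 1:20))
  expect_equal(d_tie, rep(1:10, each = 2L))
})

toy_geojson <- function(path, names) {
  square <- function(ox) list(list(
    list(ox, 0), list(ox + 1, 0), list(ox + 1, 1), list(ox, 1), list(ox, 0)))
  gj <- list(type = "FeatureCollection", features = lapply(seq_along(names),
    function(i) list(type = "Feature",
                     properties = list(name = names[i]),
                     geometry = list(type = "Polygon",
                                     coordinates = square(i - 1)))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  path
}

test_that("choropleth export joins names case-insensitively and reports misses", {
  dir <- withr::local_tempdir()
  gj <- toy_geojson(file.path(dir, "units.geojson"),
                    c("Ilocos Region", "CALABARZON", "Bicol", "Mispelt"))
  results <- tibble::tibble(
    unit1 = c("ilocos region", "Calabarzon", "BICOL", "Visayas"),
    index = c(0.3, 0.5, 0.7, 0.9))
  out <- file.path(dir, "out.geojson")
  got <- choropleth_export(results, gj, out,
                           figure_path = file.path(dir, "map.png"))
  expect_true(file.exists(out))
  expect_true(file.exists(file.path(dir, "map.png")))
  expect_equal(got$join_rate, 0.75)
  expect_equal(got$join_report$unit1[!got$join_report$matched], "Visayas")
  expect_equal(got$unmatched_features, "Mispelt")
  back <- jsonlite::fromJSON(out, simplifyVector = FALSE)
  props <- back$features[[1]]$properties
  expect_equal(props$index, 0.3)
  expect_true(props$decile %in% 1:10)
})

test_that("a join rate below half is an error naming the mismatches", {
  dir <- withr::local_tempdir()
  gj <- toy_geojson(file.path(dir, "units.geojson"), c("Aaa", "Bbb", "Ccc"))
  results <- tibble::tibble(unit1 = c("Aaa", "Xxx", "Yyy", "Zzz"),
                            index = c(0.2, 0.4, 0.6, 0.8))
  expect_error(choropleth_export(results, gj, file.path(dir, "o.geojson")),
               "Xxx")
})
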