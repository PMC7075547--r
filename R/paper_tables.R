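#' Load a packaged reference table
#'
#' The package ships the study's two printed country tables as CSV fixtures:
#' `table1` (selected characteristics: child counts, under-five mortality per
#' 1,000, mean maternal schooling) and `table2` (countries ranked by the
#' child-based capability index, with within-country unit mean and SD). Files
#' are verified against a SHA-256 manifest before parsing.
#'
#' @param name `"table1"` or `"table2"`.
#' @param dir Directory holding the fixtures and `MANIFEST.sha256`; defaults
#'   to the installed package's `extdata`.
#' @return A tibble of 55 country rows.
#' @export
load_fixture <- function(name = c("table1", "table2"), dir = NULL) {
  name <- match.arg(name)
  if (is.null(dir)) dir <- system.file("extdata", package = "childcap")
  file <- switch(name, table1 = "table1_study_countries.csv",
                 table2 = "table2_index_ranking.csv")
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("fixture not found: ", path)
  manifest <- readLines(file.path(dir, "MANIFEST.sha256"))
  expected <- sub(" .*$", "", manifest[endsWith(manifest, file)])
  actual <- digest::digest(file = path, algo = "sha256")
  if (!identical(actual, expected)) {
    stop("fixture corruption: SHA-256 mismatch for ", file)
  }
  readr::read_csv(path, show_col_types = FALSE)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Matches the typographic convention of printed tables (2.5 -> 3), unlike
#' base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Column summary statistic at printed precision
#'
#' Unweighted statistic over a fixture column, optionally rounded half-up to
#' the precision at which the table prints it.
#'
#' @param rows A fixture tibble.
#' @param column Column name.
#' @param stat `"mean"`, `"min"`, `"max"`, `"sum"` or `"sd"`.
#' @param digits Decimal places for half-up rounding, or `NULL` for none.
#' @return A single number.
#' @export
column_summary <- function(rows, column,
                           stat = c("mean", "min", "max", "sum", "sd"),
                           digits = NULL) {
  stat <- match.arg(stat)
  if (!column %in% names(rows)) stop("unknown column: ", column)
  v <- rows[[column]]
  out <- switch(stat, mean = mean(v), min = min(v), max = max(v),
                sum = sum(v), sd = sd(v))
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Recompute the printed summary cells of the reference tables
#'
#' The in-package reproduction surface: every "global average" cell and the
#' printed range statements of the two country tables, recomputed from the
#' fixtures at printed precision and compared with the values as printed.
#'
#' @return Tibble with `quantity`, `computed`, `printed`, `match`.
#' @export
reproduce_table_summaries <- function() {
  t1 <- load_fixture("table1")
  t2 <- load_fixture("table2")
  rows <- tibble::tribble(
    ~quantity,             ~computed,                                                ~printed,
    "mean_u5m_per_1000",   column_summary(t1, "u5m_per_1000", "mean", 0),            63,
    "mean_schooling_years",column_summary(t1, "maternal_schooling_years", "mean", 1), 5.6,
    "min_u5m_per_1000",    column_summary(t1, "u5m_per_1000", "min"),                6,
    "max_u5m_per_1000",    column_summary(t1, "u5m_per_1000", "max"),                156,
    "min_schooling_years", column_summary(t1, "maternal_schooling_years", "min"),    0.7,
    "max_schooling_years", column_summary(t1, "maternal_schooling_years", "max"),    12.1,
    "total_children",      column_summary(t1, "n_children", "sum"),                  1657194,
    "mean_national_index", column_summary(t2, "national_index", "mean", 3),          0.425,
    "min_national_index",  column_summary(t2, "national_index", "min"),              0.140,
    "max_national_index",  column_summary(t2, "national_index", "max"),              0.755,
    "mean_within_mean",    column_summary(t2, "within_mean", "mean", 3),             0.466,
    "mean_within_sd",      column_summary(t2, "within_sd", "mean", 3),               0.111,
    "mean_n_units",        column_summary(t2, "n_units", "mean", 0),                 12
  )
  rows$match <- abs(rows$computed - rows$printed) < 1e-9
  rows
}
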