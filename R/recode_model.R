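#' Child-record column dictionary
#'
#' The childcap tabular dialect for birth-recode style child records. One row
#' per child ever born to an interviewed woman. Dates are century-month codes
#' (CMC, months since January 1900) and are never parsed as calendars; sampling
#' weights follow the DHS convention of an integer equal to one million times
#' the design weight. The mapping from raw DHS variable names (b3, b5, b7,
#' v005, ...) to these names ships as
#' `system.file("extdata", "column_dictionary.yaml", package = "childcap")`.
#'
#' @return A tibble with columns `name`, `type` and `required`.
#' @export
child_record_columns <- function() {
  tibble::tribble(
    ~name,                       ~type,       ~required,
    "child_id",                  "character", TRUE,
    "country",                   "character", TRUE,
    "survey_year",               "integer",   TRUE,
    "unit1",                     "character", TRUE,
    "unit2",                     "character", FALSE,
    "cluster_id",                "character", TRUE,
    "household_id",              "character", TRUE,
    "mother_id",                 "character", TRUE,
    "mother_edu_years",          "integer",   TRUE,
    "mother_age_years",          "integer",   TRUE,
    "child_sex",                 "character", TRUE,
    "birth_cmc",                 "integer",   TRUE,
    "interview_cmc",             "integer",   TRUE,
    "alive",                     "character", TRUE,
    "age_at_death_months",       "integer",   TRUE,
    "weight_raw",                "integer",   TRUE,
    "wealth_quintile_provided",  "integer",   FALSE
  )
}

record_col_types <- function() {
  readr::cols(
    child_id = readr::col_character(),
    country = readr::col_character(),
    survey_year = readr::col_integer(),
    unit1 = readr::col_character(),
    unit2 = readr::col_character(),
    cluster_id = readr::col_character(),
    household_id = readr::col_character(),
    mother_id = readr::col_character(),
    mother_edu_years = readr::col_integer(),
    mother_age_years = readr::col_integer(),
    child_sex = readr::col_character(),
    birth_cmc = readr::col_integer(),
    interview_cmc = readr::col_integer(),
    alive = readr::col_character(),
    age_at_death_months = readr::col_integer(),
    weight_raw = readr::col_integer(),
    wealth_quintile_provided = readr::col_integer()
  )
}

#' Validate child records against the record-model invariants
#'
#' Rows violating a type invariant are collected into a rejects report (with a
#' reason code), never silently dropped. Invariants: interview on or after
#' birth; a death age present if and only if the child is dead; a strictly
#' positive weight; provided wealth quintile in 1..5 when present; parseable
#' integer CMC dates. `alive` values outside `"yes"`/`"no"` (DHS don't-know
#' codes) are mapped to the missing sentinel `NA` rather than rejected, so the
#' complete-case filter can account for them.
#'
#' @param df A data frame in the child-record dialect.
#' @return A list with elements `records` (valid rows, tibble) and `rejects`
#'   (invalid rows with a `reject_reason` column).
#' @export
validate_child_records <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"unit2" %in% names(df)) df$unit2 <- NA_character_
  if (!"wealth_quintile_provided" %in% names(df)) {
    df$wealth_quintile_provided <- NA_integer_
  }
  df$alive <- ifelse(df$alive %in% c("yes", "no"), df$alive, NA_character_)

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, code) ifelse(is.na(reason) & bad, code, reason)
  reason <- flag(is.na(df$birth_cmc) | is.na(df$interview_cmc), "unparseable_cmc")
  reason <- flag(!is.na(df$birth_cmc) & !is.na(df$interview_cmc) &
                   df$interview_cmc < df$birth_cmc, "interview_before_birth")
  reason <- flag(!is.na(df$alive) & df$alive == "no" &
                   is.na(df$age_at_death_months), "death_age_missing_for_dead")
  reason <- flag(!is.na(df$alive) & df$alive == "yes" &
                   !is.na(df$age_at_death_months), "death_age_present_for_alive")
  reason <- flag(is.na(df$weight_raw) | df$weight_raw <= 0, "nonpositive_weight")
  reason <- flag(!is.na(df$wealth_quintile_provided) &
                   !(df$wealth_quintile_provided %in% 1:5), "bad_wealth_quintile")

  rejects <- df[!is.na(reason), , drop = FALSE]
  rejects$reject_reason <- reason[!is.na(reason)]
  list(records = df[is.na(reason), , drop = FALSE], rejects = rejects)
}

#' Read a child-record table
#'
#' Reads the childcap child-record dialect from CSV (RFC 4180, UTF-8, header
#' row) or a columnar (parquet) file, checks the schema against
#' [child_record_columns()], and validates row-level invariants.
#'
#' @param path File to read.
#' @param dialect `"csv"` or `"parquet"`. The parquet reader requires the
#'   `arrow` package.
#' @return A list with `records` and `rejects`, as [validate_child_records()].
#' @export
read_child_records <- function(path, dialect = c("csv", "parquet")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- switch(dialect,
    csv = readr::read_csv(path, col_types = record_col_types()),
    parquet = {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop("the parquet dialect requires the 'arrow' package")
      }
      tibble::as_tibble(arrow::read_parquet(path))
    }
  )
  required <- child_record_columns()$name[child_record_columns()$required]
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  validate_child_records(df)
}

#' Write a child-record table
#'
#' @param records Child records (tibble).
#' @param path Output file.
#' @inheritParams read_child_records
#' @return `path`, invisibly.
#' @export
write_child_records <- function(records, path, dialect = c("csv", "parquet")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    csv = readr::write_csv(records, path, na = ""),
    parquet = {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop("the parquet dialect requires the 'arrow' package")
      }
      arrow::write_parquet(records, path)
    }
  )
  invisible(path)
}

#' Restrict to complete cases on the three analysis variables
#'
#' Keeps children with a non-missing survival status, non-missing maternal
#' schooling, and a resolvable household wealth measurement: a row in the
#' asset matrix for the child's household, or a provided wealth quintile in
#' pass-through mode. Exclusion counts per reason are attached as the
#' `"exclusions"` attribute and reported via `message()`.
#'
#' @param records Child records.
#' @param assets Optional asset matrix (used to resolve households). When
#'   `NULL` and not in pass-through mode, only a non-missing `household_id`
#'   is required.
#' @param use_provided_quintile Pass-through mode: require
#'   `wealth_quintile_provided` instead of asset data.
#' @return The retained records, with an `"exclusions"` attribute.
#' @export
filter_complete_case <- function(records, assets = NULL,
                                 use_provided_quintile = FALSE) {
  ok_survival <- !is.na(records$alive)
  ok_edu <- !is.na(records$mother_edu_years)
  ok_wealth <- if (use_provided_quintile) {
    !is.na(records$wealth_quintile_provided)
  } else if (!is.null(assets)) {
    records$household_id %in% assets$household_id
  } else {
    !is.na(records$household_id)
  }
  excl <- c(
    missing_survival = sum(!ok_survival),
    missing_education = sum(ok_survival & !ok_edu),
    unresolved_wealth = sum(ok_survival & ok_edu & !ok_wealth)
  )
  out <- records[ok_survival & ok_edu & ok_wealth, , drop = FALSE]
  if (sum(excl) > 0) {
    message("complete-case filter excluded ", sum(excl), " record(s): ",
            paste(names(excl), excl, sep = "=", collapse = ", "))
  }
  attr(out, "exclusions") <- excl
  out
}

#' Restrict to children born within a window before the interview
#'
#' "Born in the past k years" is read as strictly fewer than 12 k months
#' between birth and interview (half-open interval; CMC arithmetic is exact).
#'
#' @param records Child records.
#' @param window `"years_10"` (default analysis), `"years_5"` or
#'   `"full_history"`.
#' @return The retained records.
#' @export
filter_birth_window <- function(records,
                                window = c("years_10", "years_5", "full_history")) {
  window <- match.arg(window)
  if (window == "full_history") return(records)
  k <- if (window == "years_10") 10L else 5L
  age_months <- records$interview_cmc - records$birth_cmc
  records[age_months < 12L * k, , drop = FALSE]
}

#' Restrict to children of mothers in an age band
#'
#' @param records Child records.
#' @param min_age,max_age Inclusive bounds on mother's age at interview, years.
#' @return The retained records.
#' @export
filter_maternal_age <- function(records, min_age = 15L, max_age = 49L) {
  if (min_age > max_age) stop("min_age must not exceed max_age")
  keep <- records$mother_age_years >= min_age & records$mother_age_years <= max_age
  records[keep, , drop = FALSE]
}

survival_before <- function(records, cutoff_months, label) {
  if (anyNA(records$alive)) {
    stop("survival coding requires a non-missing survival status for every ",
         "record; run filter_complete_case() first (", label, ")")
  }
  dead_young <- records$alive == "no" &
    records$age_at_death_months < cutoff_months
  as.integer(!dead_young)
}

#' Code under-five survival
#'
#' Returns 0 for children who died before 60 completed months and 1 otherwise.
#' A death at or after the fifth birthday is not an under-five death. Living
#' children currently younger than five count as survivors (binary
#' alive-at-interview coding; no life-table correction).
#'
#' @param records Complete-case child records.
#' @return Integer vector of 0/1 survival indicators.
#' @export
code_under_five_survival <- function(records) {
  survival_before(records, 60L, "under-five survival")
}

#' Code infant survival
#'
#' Returns 0 for children who died before 12 completed months and 1 otherwise.
#'
#' @inheritParams code_under_five_survival
#' @return Integer vector of 0/1 survival indicators.
#' @export
code_infant_survival <- function(records) {
  survival_before(records, 12L, "infant survival")
}
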