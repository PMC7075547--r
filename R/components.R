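#' Aggregate child-level data into country/unit cells
#'
#' Computes, for each cell, the survey-weighted survival share, mean maternal
#' schooling and mean wealth quintile (weights `weight_raw / 1e6`, the DHS
#' convention), plus the implied mortality per 1,000. Cells with fewer
#' children than `low_n_floor` are flagged `low_n` rather than suppressed.
#'
#' @param records Filtered child records with an assigned `wealth_quintile`.
#' @param level `"national"`, `"unit1"` or `"unit2"`.
#' @param survival_coder `"under_five"` (death before 60 completed months) or
#'   `"infant"` (before 12).
#' @param group_by_sex Additionally split cells by child sex.
#' @param low_n_floor Minimum cell size before flagging.
#' @return Tibble of cells: keys, `n_children`, `survival_bar`,
#'   `education_bar`, `wealth_bar`, `u5m_per_1000`, `low_n`.
#' @export
aggregate_components <- function(records,
                                 level = c("national", "unit1", "unit2"),
                                 survival_coder = c("under_five", "infant"),
                                 group_by_sex = FALSE,
                                 low_n_floor = 25L) {
  level <- match.arg(level)
  survival_coder <- match.arg(survival_coder)
  if (nrow(records) == 0L) stop("no records to aggregate")
  if (!"wealth_quintile" %in% names(records)) {
    stop("records carry no wealth_quintile; assign quintiles first")
  }
  if (level == "unit2" && all(is.na(records$unit2))) {
    stop("unknown unit label: unit2 is missing from these records")
  }
  s <- switch(survival_coder,
              under_five = code_under_five_survival(records),
              infant = code_infant_survival(records))
  keys <- switch(level,
                 national = "country",
                 unit1 = c("country", "unit1"),
                 unit2 = c("country", "unit1", "unit2"))
  if (group_by_sex) keys <- c(keys, "child_sex")
  df <- records[, keys, drop = FALSE]
  df$s <- s
  df$e <- records$mother_edu_years
  df$q <- records$wealth_quintile
  df$w <- records$weight_raw / 1e6
  out <- dplyr::summarise(
    dplyr::group_by(df, dplyr::across(dplyr::all_of(keys))),
    n_children = dplyr::n(),
    survival_bar = sum(.data$w * .data$s) / sum(.data$w),
    education_bar = sum(.data$w * .data$e) / sum(.data$w),
    wealth_bar = sum(.data$w * .data$q) / sum(.data$w),
    weight_total = sum(.data$w),
    .groups = "drop"
  )
  out$u5m_per_1000 <- 1000 * (1 - out$survival_bar)
  out$low_n <- out$n_children < low_n_floor
  out
}
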