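#' Asset-based household wealth scores
#'
#' Scores each household by the first principal component of the standardized
#' binary asset/dwelling-quality indicator matrix, computed over the scoring
#' stratum: all countries pooled (for cross-country comparison) or each
#' country separately (for within-country comparison). The component sign is
#' oriented so the sum of indicator loadings is positive — owning more assets
#' always raises the score. Constant columns carry no information and are
#' dropped with a warning.
#'
#' @param assets Asset matrix: `household_id`, `country`, binary `asset_*`
#'   columns, and optionally `household_weight`.
#' @param scope `"pooled"` or `"within_country"`.
#' @return Tibble `household_id`, `country`, `scope`, `score`.
#' @export
compute_wealth_scores <- function(assets, scope = c("pooled", "within_country")) {
  scope <- match.arg(scope)
  cols <- grep("^asset_", names(assets), value = TRUE)
  if (length(cols) < 2L) stop("wealth scoring needs >= 2 indicator columns")
  score_stratum <- function(df) {
    x <- as.matrix(df[, cols])
    if (!all(x %in% c(0, 1))) stop("asset indicators must be binary 0/1")
    keep <- apply(x, 2L, function(col) stats::var(col) > 0)
    if (sum(keep) < 2L) {
      stop("fewer than 2 non-constant indicator columns in stratum")
    }
    if (any(!keep)) {
      warning("dropping constant indicator column(s): ",
              paste(cols[!keep], collapse = ", "))
    }
    if (nrow(x) < 3L) stop("wealth scoring needs >= 3 households per stratum")
    pc <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
    score <- pc$x[, 1L]
    if (sum(pc$rotation[, 1L]) < 0) score <- -score
    tibble::tibble(household_id = df$household_id, country = df$country,
                   scope = scope, score = unname(score))
  }
  if (scope == "pooled") {
    score_stratum(assets)
  } else {
    dplyr::bind_rows(lapply(split(assets, assets$country), score_stratum))
  }
}

#' Weighted quantiles by inversion of the weighted empirical CDF
#'
#' Returns, for each probability, the smallest observed value whose cumulative
#' normalized weight reaches it. With equal weights this is quantile type 1.
#'
#' @param x Numeric values.
#' @param w Positive weights.
#' @param probs Probabilities in (0, 1).
#' @return Numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w > 0), all(probs > 0 & probs < 1))
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[ord][which(cw >= p - 1e-12)[1L]], numeric(1))
}

#' Assign wealth quintiles over the child-level distribution
#'
#' Cut points are the survey-weighted 20/40/60/80% quantiles of the household
#' score over the child-level distribution (each child contributes its own
#' sampling weight), so roughly a fifth of children — not of households —
#' falls in each quintile. A household sitting exactly on a cut point goes to
#' the lower quintile; all children of a household share its quintile.
#'
#' @param scores Household scores from [compute_wealth_scores()].
#' @param children Child records linked to the scored households.
#' @param by Stratification for the cut points: `"pooled"` (one set of cut
#'   points) or `"within_country"`.
#' @return `children` with `wealth_score` and `wealth_quintile` columns.
#' @export
assign_quintiles <- function(children, scores,
                             by = c("pooled", "within_country")) {
  by <- match.arg(by)
  missing_hh <- setdiff(children$household_id, scores$household_id)
  if (length(missing_hh) > 0) {
    stop("no wealth score for ", length(missing_hh), " household(s), e.g. ",
         missing_hh[1L])
  }
  out <- dplyr::left_join(children,
                          scores[, c("household_id", "score")],
                          by = "household_id")
  out <- dplyr::rename(out, wealth_score = "score")
  cut_one <- function(df) {
    s <- df$wealth_score
    w <- df$weight_raw / 1e6
    if (diff(range(s)) == 0) {
      warning("all wealth scores equal; assigning quintile 3 throughout")
      df$wealth_quintile <- 3L
      return(df)
    }
    cuts <- weighted_quantile(s, w, c(0.2, 0.4, 0.6, 0.8))
    df$wealth_quintile <- 1L + (s > cuts[1]) + (s > cuts[2]) +
      (s > cuts[3]) + (s > cuts[4])
    df
  }
  if (by == "pooled") cut_one(out)
  else dplyr::bind_rows(lapply(split(out, out$country), cut_one))
}

#' Attach DHS-provided wealth quintiles (pass-through mode)
#'
#' Sensitivity variant: skip asset scoring and use the survey's own wealth
#' quintile column directly.
#'
#' @param children Child records with `wealth_quintile_provided`.
#' @return `children` with a `wealth_quintile` column.
#' @export
use_provided_quintiles <- function(children) {
  if (anyNA(children$wealth_quintile_provided)) {
    stop("wealth_quintile_provided is missing for some records; ",
         "run filter_complete_case(use_provided_quintile = TRUE) first")
  }
  children$wealth_quintile <- as.integer(children$wealth_quintile_provided)
  children
}
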