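#' Configuration for the synthetic DHS-like survey generator
#'
#' Defaults emulate the study conditions of the 55-country analysis at test
#' scale: per-unit under-five death probabilities spanning the observed
#' national range of 6-156 per 1,000, unit mean maternal schooling spanning
#' 0.7-12.1 years, binary assets loading on a latent household wealth factor,
#' clustered households with lognormal DHS-style integer weights, and mothers
#' aged 15-49 carrying multi-child birth histories. The default size (10
#' countries x 6 units, roughly 2,000 children per unit inside the ten-year
#' window) is the parameter-recovery design used throughout the test suite.
#'
#' @param n_countries Number of countries.
#' @param units_per_country First-level administrative units per country
#'   (single count or vector of length `n_countries`).
#' @param clusters_per_unit,households_per_cluster Sampling hierarchy sizes;
#'   one interviewed mother per household.
#' @param u5m_range Range of per-unit under-five death probabilities, drawn
#'   uniformly.
#' @param edu_mean_range Range of per-unit mean maternal schooling, years.
#' @param edu_dispersion SD (years) of schooling around its mother-level
#'   center before discretization.
#' @param n_assets Number of binary asset/dwelling indicators.
#' @param asset_loading_range Range of logit slopes of indicators on latent
#'   wealth, drawn uniformly; in (0, 1].
#' @param weight_cv Coefficient of variation of the lognormal cluster weights.
#' @param fertility_mean Mean births per mother inside the ten-year window for
#'   a mother whose reproductive span covers the full window.
#' @param edu_wealth_slope Years of schooling per SD of household latent
#'   wealth (education-wealth correlation at the mother level).
#' @param mortality_edu_logit Logit shift in a child's death probability per
#'   year of maternal schooling above the unit mean (small and negative).
#' @param two_rounds Generate a second survey round.
#' @param round_gap_years Years between the two rounds.
#' @param u5m_trend Multiplicative change in unit death probabilities between
#'   rounds (0.8 = 20% decline).
#' @param seed Integer seed; a fixed seed makes the survey reproducible.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_countries = 10L,
                             units_per_country = 6L,
                             clusters_per_unit = 40L,
                             households_per_cluster = 20L,
                             u5m_range = c(0.006, 0.156),
                             edu_mean_range = c(0.7, 12.1),
                             edu_dispersion = 2.5,
                             n_assets = 30L,
                             asset_loading_range = c(0.4, 1.0),
                             weight_cv = 0.25,
                             fertility_mean = 3.0,
                             edu_wealth_slope = 1.0,
                             mortality_edu_logit = -0.05,
                             two_rounds = FALSE,
                             round_gap_years = 10L,
                             u5m_trend = 0.8,
                             seed = 20200316L) {
  cfg <- list(
    n_countries = as.integer(n_countries),
    units_per_country = as.integer(units_per_country),
    clusters_per_unit = as.integer(clusters_per_unit),
    households_per_cluster = as.integer(households_per_cluster),
    u5m_range = as.numeric(u5m_range),
    edu_mean_range = as.numeric(edu_mean_range),
    edu_dispersion = as.numeric(edu_dispersion),
    n_assets = as.integer(n_assets),
    asset_loading_range = as.numeric(asset_loading_range),
    weight_cv = as.numeric(weight_cv),
    fertility_mean = as.numeric(fertility_mean),
    edu_wealth_slope = as.numeric(edu_wealth_slope),
    mortality_edu_logit = as.numeric(mortality_edu_logit),
    two_rounds = isTRUE(two_rounds),
    round_gap_years = as.integer(round_gap_years),
    u5m_trend = as.numeric(u5m_trend),
    seed = as.integer(seed)
  )
  counts <- c(cfg$n_countries, cfg$units_per_country, cfg$clusters_per_unit,
              cfg$households_per_cluster, cfg$n_assets)
  if (any(counts < 1L)) stop("all generator counts must be >= 1")
  if (!(length(cfg$units_per_country) %in% c(1L, cfg$n_countries))) {
    stop("units_per_country must be a single count or one per country")
  }
  if (any(cfg$u5m_range < 0) || any(cfg$u5m_range > 1) ||
      cfg$u5m_range[1] > cfg$u5m_range[2]) {
    stop("u5m_range must be an ordered pair of probabilities")
  }
  if (any(cfg$asset_loading_range <= 0) || any(cfg$asset_loading_range > 1)) {
    stop("asset_loading_range must lie in (0, 1]")
  }
  if (cfg$fertility_mean <= 0) {
    stop("degenerate config: zero births expected (fertility_mean <= 0)")
  }
  structure(cfg, class = "generator_config")
}

# exact expected value of round(y) with y ~ N(center, sd) truncated at y >= -0.5
truncated_round_mean <- function(center, sd, kmax = 60L) {
  denom <- 1 - pnorm((-0.5 - center) / sd)
  ks <- seq_len(kmax)
  tails <- vapply(ks, function(k) 1 - pnorm((k - 0.5 - center) / sd),
                  numeric(length(center)))
  if (length(center) == 1L) tails <- matrix(tails, nrow = 1L)
  rowSums(tails) / denom
}

# draw round(y), y ~ N(center, sd) truncated at -0.5, by inverse-CDF sampling
draw_discrete_education <- function(center, sd) {
  lo <- pnorm((-0.5 - center) / sd)
  u <- lo + runif(length(center)) * (1 - lo)
  pmax(0L, as.integer(round(center + sd * qnorm(u))))
}

generate_round <- function(cfg, round_id, survey_year, loadings, intercepts,
                           units = NULL) {
  n_units <- if (length(cfg$units_per_country) == 1L) {
    rep(cfg$units_per_country, cfg$n_countries)
  } else cfg$units_per_country
  countries <- sprintf("C%02d", seq_len(cfg$n_countries))
  interview_cmc <- (survey_year - 1900L) * 12L + 6L

  if (is.null(units)) {
    units <- tibble::tibble(
      country = rep(countries, n_units),
      unit1 = unlist(lapply(n_units, function(k) sprintf("U%02d", seq_len(k))))
    )
    units$p_unit <- runif(nrow(units), cfg$u5m_range[1], cfg$u5m_range[2])
    units$edu_mean_unit <- runif(nrow(units), cfg$edu_mean_range[1],
                                 cfg$edu_mean_range[2])
    units$wealth_mean_unit <- rnorm(nrow(units), 0, 0.6)
  }

  # clusters: lognormal design weights with the configured CV, mean 1
  s2 <- log(1 + cfg$weight_cv^2)
  clusters <- units[rep(seq_len(nrow(units)), each = cfg$clusters_per_unit), ]
  clusters$cluster_seq <- sprintf("%03d", sequence(rep(cfg$clusters_per_unit,
                                                       nrow(units))))
  clusters$cluster_weight <- rlnorm(nrow(clusters), -s2 / 2, sqrt(s2))

  # households: one interviewed mother each, latent wealth around the unit mean
  hh <- clusters[rep(seq_len(nrow(clusters)),
                     each = cfg$households_per_cluster), ]
  hh$hh_seq <- sprintf("%03d", sequence(rep(cfg$households_per_cluster,
                                            nrow(clusters))))
  hh$cluster_id <- paste(hh$country, hh$unit1, hh$cluster_seq, round_id,
                         sep = "-")
  hh$household_id <- paste(hh$cluster_id, hh$hh_seq, sep = "-")
  hh$wealth_latent <- rnorm(nrow(hh), hh$wealth_mean_unit, 1)
  hh$mother_age_years <- sample(15:49, nrow(hh), replace = TRUE,
                                prob = stats::dnorm(15:49, 28, 8))
  edu_center <- hh$edu_mean_unit +
    cfg$edu_wealth_slope * (hh$wealth_latent - hh$wealth_mean_unit)
  hh$mother_edu_years <- draw_discrete_education(edu_center, cfg$edu_dispersion)
  hh$edu_expected <- truncated_round_mean(edu_center, cfg$edu_dispersion)

  # asset indicators: independent Bernoulli given latent wealth
  eta <- outer(hh$wealth_latent, loadings) +
    matrix(intercepts, nrow(hh), cfg$n_assets, byrow = TRUE)
  amat <- matrix(rbinom(length(eta), 1L, plogis(eta)), nrow(hh))
  colnames(amat) <- sprintf("asset_%02d", seq_len(cfg$n_assets))
  assets <- dplyr::bind_cols(
    tibble::tibble(household_id = hh$household_id, country = hh$country,
                   household_weight = hh$cluster_weight),
    tibble::as_tibble(amat)
  )

  # birth histories: window births at the full rate, earlier births pro rata
  span <- pmin((hh$mother_age_years - 15L) * 12L, interview_cmc - 1L)
  rate <- cfg$fertility_mean / 120
  n_window <- rpois(nrow(hh), rate * pmin(span, 120L))
  n_pre <- rpois(nrow(hh), rate * pmax(span - 120L, 0L))
  n_births <- n_window + n_pre
  if (sum(n_births) == 0L) stop("degenerate config: zero births generated")

  idx <- rep(seq_len(nrow(hh)), n_births)
  kids <- hh[idx, c("country", "unit1", "cluster_id", "household_id",
                    "cluster_weight", "p_unit", "edu_mean_unit",
                    "mother_age_years", "mother_edu_years", "edu_expected",
                    "wealth_latent")]
  in_window <- sequence(n_births) <= rep(n_window, n_births)
  span_k <- rep(span, n_births)
  age_months <- ifelse(
    in_window,
    1L + floor(runif(nrow(kids)) * pmin(span_k, 120L)),
    121L + floor(runif(nrow(kids)) * pmax(span_k - 120L, 1L))
  )
  age_months <- pmin(as.integer(age_months), as.integer(span_k))
  kids$birth_cmc <- interview_cmc - age_months
  kids$interview_cmc <- interview_cmc

  # survival: alive-at-interview binary with a maternal-education logit shift
  p_die <- plogis(qlogis(kids$p_unit) + cfg$mortality_edu_logit *
                    (kids$mother_edu_years - kids$edu_mean_unit))
  kids$p_die5 <- p_die
  died5 <- rbinom(nrow(kids), 1L, p_die) == 1L
  infant <- runif(nrow(kids)) < 0.55
  raw_death_age <- ifelse(infant, floor(12 * runif(nrow(kids))),
                          12L + floor(48 * runif(nrow(kids))))
  death_age <- pmin(as.integer(raw_death_age), age_months)
  # a few deaths after the fifth birthday: not under-five deaths
  late <- !died5 & age_months > 60L & runif(nrow(kids)) < 0.02
  late_age <- 60L + floor(runif(nrow(kids)) * pmax(age_months - 60L, 1L))

  kids$alive <- ifelse(died5 | late, "no", "yes")
  kids$age_at_death_months <- ifelse(died5, death_age,
                                     ifelse(late, as.integer(late_age),
                                            NA_integer_))
  kids$child_sex <- sample(c("male", "female"), nrow(kids), replace = TRUE)
  kids$weight_raw <- pmax(1L, as.integer(round(kids$cluster_weight * 1e6)))
  kids$survey_year <- survey_year
  kids$mother_id <- kids$household_id
  kids$unit2 <- NA_character_
  kids$wealth_quintile_provided <- NA_integer_
  kids <- dplyr::group_by(kids, .data$household_id)
  kids <- dplyr::mutate(kids, child_id = paste(.data$household_id,
                                               dplyr::row_number(), sep = "-"))
  kids <- dplyr::ungroup(kids)

  # truth is defined over the ten-year-window children: the estimands of the
  # default aggregation
  win <- (kids$interview_cmc - kids$birth_cmc) < 120L
  kw <- kids[win, , drop = FALSE]
  ww <- kw$weight_raw / 1e6
  truth_cells <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(
      country = kw$country, unit1 = kw$unit1, w = ww,
      s = 1 - kw$p_die5, e = kw$edu_expected, wl = kw$wealth_latent
    ), .data$country, .data$unit1),
    survival_true = sum(.data$w * .data$s) / sum(.data$w),
    edu_true = sum(.data$w * .data$e) / sum(.data$w),
    wealth_latent_true = sum(.data$w * .data$wl) / sum(.data$w),
    .groups = "drop"
  )
  truth_cells$survey_year <- survey_year
  truth_cells <- dplyr::left_join(truth_cells,
                                  units[, c("country", "unit1", "p_unit",
                                            "edu_mean_unit")],
                                  by = c("country", "unit1"))

  record_cols <- c("child_id", "country", "survey_year", "unit1", "unit2",
                   "cluster_id", "household_id", "mother_id",
                   "mother_edu_years", "mother_age_years", "child_sex",
                   "birth_cmc", "interview_cmc", "alive",
                   "age_at_death_months", "weight_raw",
                   "wealth_quintile_provided")
  list(
    records = kids[, record_cols],
    assets = assets,
    units = units,
    truth_cells = truth_cells,
    households = tibble::tibble(household_id = hh$household_id,
                                country = hh$country, unit1 = hh$unit1,
                                survey_year = survey_year,
                                wealth_latent = hh$wealth_latent),
    meta = tibble::tibble(
      country = countries, survey_year = survey_year,
      n_units1 = n_units, label_units1 = "Provinces"
    )
  )
}

#' Generate a synthetic DHS-like survey with known ground truth
#'
#' Hierarchical sampling: administrative units receive true under-five death
#' probabilities, mean schooling and latent wealth levels; clusters receive
#' lognormal design weights; households receive a latent wealth draw, one
#' interviewed mother (aged 15-49) whose schooling is a discretized truncated
#' normal correlated with household wealth, and a multi-child birth history;
#' each child's alive-at-interview status is Bernoulli with a logit shift in
#' the death probability by maternal schooling; binary assets are independent
#' Bernoulli given latent wealth. Deterministic under the configured seed.
#'
#' The returned `truth` holds, per (country, unit, round): the exact expected
#' survey-weighted survival share, expected mean schooling (exact mean of the
#' discretized truncated normal), and weighted latent-wealth mean, over
#' children born inside the ten-year window — the estimands of the default
#' aggregation — plus the drawn unit parameters. Per-household latent wealth
#' is stored alongside.
#'
#' @param config A [generator_config()].
#' @return A list with `records` (child-record dialect tibble), `assets`
#'   (household x asset matrix with weights), `truth` (list: `cells`,
#'   `households`), and `meta` (per-country survey metadata).
#' @export
generate_survey <- function(config) {
  if (!inherits(config, "generator_config")) config <- do.call(generator_config, config)
  withr::with_seed(config$seed, {
    loadings <- runif(config$n_assets, config$asset_loading_range[1],
                      config$asset_loading_range[2])
    intercepts <- runif(config$n_assets, -1.5, 1.5)
    r1 <- generate_round(config, "r1", 2005L, loadings, intercepts)
    if (config$two_rounds) {
      # round 2 revisits the same units; only mortality moves, by the trend
      units2 <- r1$units
      units2$p_unit <- pmin(0.95, units2$p_unit * config$u5m_trend)
      r2 <- generate_round(config, "r2", 2005L + config$round_gap_years,
                           loadings, intercepts, units = units2)
      list(
        records = dplyr::bind_rows(r1$records, r2$records),
        assets = dplyr::bind_rows(r1$assets, r2$assets),
        truth = list(cells = dplyr::bind_rows(r1$truth_cells, r2$truth_cells),
                     households = dplyr::bind_rows(r1$households, r2$households)),
        meta = dplyr::bind_rows(r1$meta, r2$meta)
      )
    } else {
      list(records = r1$records, assets = r1$assets,
           truth = list(cells = r1$truth_cells, households = r1$households),
           meta = r1$meta)
    }
  })
}
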