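#' Default fixed goalposts for the three components
#'
#' Natural bounds: survival share in \[0, 1\], maternal schooling in \[0, 15\]
#' years (15 years as the upper reference value), wealth quintile in \[1, 5\].
#'
#' @return Named list of `c(lower, upper)` pairs for `U5S`, `Edu`, `Wealth`.
#' @export
default_goalposts <- function() {
  list(U5S = c(0, 1), Edu = c(0, 15), Wealth = c(1, 5))
}

component_column <- function(component) {
  switch(component, U5S = "survival_bar", Edu = "education_bar",
         Wealth = "wealth_bar")
}

#' Normalization bounds for one component
#'
#' Either the observed extrema of the component over the supplied cells (the
#' literal min-max rescaling, used for subnational visualization) or fixed
#' goalposts (the default for national index tables; see the vignette for why
#' observed extrema force the minimum country to an index of zero).
#'
#' @param cells Cell aggregates (used in `observed_extrema` mode).
#' @param component `"U5S"`, `"Edu"` or `"Wealth"`.
#' @param scope Bookkeeping label: `"across_countries"` or
#'   `"within_country_units"`.
#' @param mode `"observed_extrema"` or `"fixed_goalposts"`.
#' @param goalposts `c(lower, upper)` for `fixed_goalposts`; defaults to
#'   [default_goalposts()].
#' @return A `normalization_bounds` list: `component`, `lower`, `upper`,
#'   `scope`, `mode`.
#' @export
compute_bounds <- function(cells = NULL,
                           component = c("U5S", "Edu", "Wealth"),
                           scope = c("across_countries", "within_country_units"),
                           mode = c("observed_extrema", "fixed_goalposts"),
                           goalposts = NULL) {
  component <- match.arg(component)
  scope <- match.arg(scope)
  mode <- match.arg(mode)
  if (mode == "observed_extrema") {
    col <- component_column(component)
    if (is.null(cells) || nrow(cells) < 2L) {
      stop("observed_extrema needs >= 2 cells")
    }
    v <- cells[[col]]
    lo <- min(v); hi <- max(v)
    if (lo == hi) {
      stop("degenerate extrema (min = max) for ", component,
           "; use fixed goalposts instead")
    }
  } else {
    gp <- if (is.null(goalposts)) default_goalposts()[[component]] else goalposts
    lo <- gp[1]; hi <- gp[2]
    if (!(hi > lo)) stop("goalposts must satisfy upper > lower")
  }
  structure(list(component = component, lower = lo, upper = hi,
                 scope = scope, mode = mode),
            class = "normalization_bounds")
}

#' Min-max (goalpost) rescaling of a component value to \[0, 1\]
#'
#' `(value - lower) / (upper - lower)`. With `clamp` on (the default under
#' fixed goalposts), values outside the bounds are clamped to \[0, 1\] with a
#' warning; with clamping off they raise a range error.
#'
#' @param value Numeric vector.
#' @param bounds A `normalization_bounds` object from [compute_bounds()].
#' @param clamp Clamp out-of-range results instead of erroring.
#' @return Numeric vector in \[0, 1\].
#' @export
normalize_indicator <- function(value, bounds,
                                clamp = bounds$mode == "fixed_goalposts") {
  z <- (value - bounds$lower) / (bounds$upper - bounds$lower)
  out_of_range <- z < 0 | z > 1
  if (any(out_of_range)) {
    if (!clamp) {
      stop("value outside normalization bounds for ", bounds$component,
           " (and clamping is off)")
    }
    warning(sum(out_of_range), " ", bounds$component,
            " value(s) outside goalposts; clamped to [0, 1]")
    z <- pmin(1, pmax(0, z))
  }
  z
}

#' Combine three normalized components into the capability index
#'
#' Geometric mean (cube root of the product; a zero in any dimension yields
#' an index of zero, so low achievements cannot be linearly compensated) or
#' the arithmetic-mean sensitivity variant.
#'
#' @param u5s,edu,wealth Normalized components in \[0, 1\] (vectorized).
#' @param mean_type `"geometric"` or `"arithmetic"`.
#' @return Numeric index in \[0, 1\].
#' @export
compute_index <- function(u5s, edu, wealth,
                          mean_type = c("geometric", "arithmetic")) {
  mean_type <- match.arg(mean_type)
  vals <- cbind(u5s, edu, wealth)
  if (any(vals < 0 | vals > 1, na.rm = TRUE)) {
    stop("normalized components must lie in [0, 1]")
  }
  if (mean_type == "geometric") (u5s * edu * wealth)^(1 / 3)
  else (u5s + edu + wealth) / 3
}

#' Mean and dispersion of unit-level indices within one country
#'
#' Unweighted mean across first-level units and the sample SD (n - 1
#' denominator, configurable). With a single unit the SD is undefined and
#' returned as `NA` with a flag.
#'
#' @param index Unit-level index values for one country.
#' @param denominator `"n-1"` (sample SD, default) or `"n"`.
#' @return List `mean`, `sd`, `n_units`, `sd_defined`.
#' @export
within_country_stats <- function(index, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  n <- length(index)
  m <- mean(index)
  s <- if (n < 2L) NA_real_ else if (denominator == "n-1") sd(index)
       else sqrt(mean((index - m)^2))
  list(mean = m, sd = s, n_units = n, sd_defined = n >= 2L)
}

#' Build the index table for a set of cells
#'
#' Normalizes the three components with the supplied bounds, combines them
#' into the capability index, and (for national cells) ranks countries by
#' descending index with alphabetical tie-breaking.
#'
#' @param cells Cell aggregates from [aggregate_components()].
#' @param bounds Named list with `U5S`, `Edu`, `Wealth` bounds sharing scope
#'   and mode; defaults to fixed natural goalposts.
#' @param mean_type `"geometric"` or `"arithmetic"`.
#' @return `cells` plus `u5s_norm`, `edu_norm`, `wealth_norm`, `index`, and
#'   `rank` for national tables.
#' @export
build_index_table <- function(cells, bounds = NULL,
                              mean_type = c("geometric", "arithmetic")) {
  mean_type <- match.arg(mean_type)
  if (is.null(bounds)) {
    bounds <- lapply(setNames(nm = c("U5S", "Edu", "Wealth")), function(cmp)
      compute_bounds(component = cmp, mode = "fixed_goalposts"))
  }
  stopifnot(all(c("U5S", "Edu", "Wealth") %in% names(bounds)))
  scopes <- vapply(bounds, `[[`, "", "scope")
  if (length(unique(scopes)) != 1L) {
    stop("scope mismatch: the three bounds must share a scope")
  }
  out <- cells
  out$u5s_norm <- normalize_indicator(cells$survival_bar, bounds$U5S)
  out$edu_norm <- normalize_indicator(cells$education_bar, bounds$Edu)
  out$wealth_norm <- normalize_indicator(cells$wealth_bar, bounds$Wealth)
  out$index <- compute_index(out$u5s_norm, out$edu_norm, out$wealth_norm,
                             mean_type)
  out$mean_type <- mean_type
  if (!"unit1" %in% names(out)) {
    out <- out[order(-out$index, out$country), , drop = FALSE]
    out$rank <- seq_len(nrow(out))
  }
  out
}

#' Within-country summary of a unit-level index table
#'
#' @param unit_index Unit-level table from [build_index_table()].
#' @inheritParams within_country_stats
#' @return One row per country: `n_units`, `within_mean`, `within_sd`,
#'   `sd_defined`.
#' @export
within_country_summary <- function(unit_index, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  stopifnot("unit1" %in% names(unit_index))
  dplyr::bind_rows(lapply(split(unit_index, unit_index$country), function(df) {
    st <- within_country_stats(df$index, denominator)
    tibble::tibble(country = df$country[1L], n_units = st$n_units,
                   within_mean = st$mean, within_sd = st$sd,
                   sd_defined = st$sd_defined)
  }))
}
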