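#' Pearson correlation between two matched index vectors
#'
#' Product-moment correlation with the two-sided test of independence.
#'
#' @param x,y Numeric vectors of equal length (matched pairs).
#' @return List `r`, `p_value`, `n_pairs`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in one of the vectors")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_pairs = length(x))
}

#' Compare the capability index with an external index
#'
#' Joins an external two-column index table (e.g. HDI, Human Capital Index or
#' Socio-Demographic Index values keyed by country) to a national index table
#' and reports the Pearson correlation over matched countries.
#'
#' @param index_table National index table with `country` and `index`.
#' @param external Tibble with `country` and a value column.
#' @param value_col Name of the external value column (default: second
#'   column).
#' @return List `pairs` (matched tibble), `r`, `p_value`, `n_pairs`,
#'   `unmatched` (countries found on only one side).
#' @export
compare_indices <- function(index_table, external, value_col = NULL) {
  if (is.null(value_col)) value_col <- setdiff(names(external), "country")[1L]
  pairs <- dplyr::inner_join(index_table[, c("country", "index")],
                             external[, c("country", value_col)],
                             by = "country")
  unmatched <- c(setdiff(index_table$country, external$country),
                 setdiff(external$country, index_table$country))
  res <- pearson_correlation(pairs$index, pairs[[value_col]])
  c(list(pairs = pairs, unmatched = unmatched), res)
}

#' Per-unit change between two survey rounds
#'
#' Matches unit-level results of two rounds on their cell keys and reports
#' per-unit deltas for every shared numeric column; units present in only one
#' round are reported, never silently dropped.
#'
#' @param results_t0,results_t1 Unit-level tables (cells or index results).
#' @param match_on Key columns, default `c("country", "unit1")`.
#' @return List `deltas` (keys + `delta_*` columns), `unmatched` (keys with a
#'   `round` column), `summary` (median delta per column).
#' @export
round_change <- function(results_t0, results_t1,
                         match_on = c("country", "unit1")) {
  num_cols <- intersect(
    names(results_t0)[vapply(results_t0, is.numeric, TRUE)],
    names(results_t1)[vapply(results_t1, is.numeric, TRUE)]
  )
  num_cols <- setdiff(num_cols, match_on)
  joined <- dplyr::inner_join(results_t0[, c(match_on, num_cols)],
                              results_t1[, c(match_on, num_cols)],
                              by = match_on, suffix = c("_t0", "_t1"))
  if (nrow(joined) == 0L) stop("zero matched units between rounds")
  deltas <- joined[, match_on, drop = FALSE]
  for (col in num_cols) {
    deltas[[paste0("delta_", col)]] <-
      joined[[paste0(col, "_t1")]] - joined[[paste0(col, "_t0")]]
  }
  only_t0 <- dplyr::anti_join(results_t0[, match_on], results_t1[, match_on],
                              by = match_on)
  only_t1 <- dplyr::anti_join(results_t1[, match_on], results_t0[, match_on],
                              by = match_on)
  unmatched <- dplyr::bind_rows(
    if (nrow(only_t0)) dplyr::mutate(only_t0, round = "t0_only"),
    if (nrow(only_t1)) dplyr::mutate(only_t1, round = "t1_only")
  )
  summary <- vapply(num_cols, function(col)
    stats::median(deltas[[paste0("delta_", col)]]), numeric(1))
  list(deltas = deltas, unmatched = unmatched, summary = summary)
}

tps_kernel <- function(r) ifelse(r > 0, r^2 * log(r), 0)

#' Interpolate the development-spectrum surface onto a regular grid
#'
#' Builds the contour surface with normalized wealth on x, normalized
#' education on y, and survival as the interpolated z. Thin-plate-spline
#' radial-basis interpolation (kernel r^2 log r plus affine terms) reproduces
#' the source points exactly; interpolated values are clipped to the observed
#' z range and the contour levels are ten (by default) equal-width bins of
#' that range. Collinear (x, y) points make the thin-plate system singular;
#' they fall back to a least-squares affine surface with a warning (exact
#' whenever the points are coplanar).
#'
#' @param points Data frame with numeric `x`, `y`, `z` (one row per cell).
#' @param resolution Grid nodes per axis.
#' @param n_levels Number of contour levels.
#' @param interpolation `"thin_plate_rbf"` or `"linear"`.
#' @return A `contour_grid`: `x`, `y` (node coordinates), `z` (matrix,
#'   rows = x), `levels`, `points`, `method`.
#' @export
build_contour_grid <- function(points, resolution = 50L, n_levels = 10L,
                               interpolation = c("thin_plate_rbf", "linear")) {
  interpolation <- match.arg(interpolation)
  stopifnot(all(c("x", "y", "z") %in% names(points)))
  pts <- tibble::as_tibble(points[, c("x", "y", "z")])
  if (nrow(pts) < 3L) stop("need at least 3 source points")
  if (anyDuplicated(pts[, c("x", "y")])) stop("duplicate (x, y) source points")
  collinear <- qr(cbind(1, pts$x, pts$y))$rank < 3L
  if (interpolation == "thin_plate_rbf" && collinear) {
    warning("source points are collinear; falling back to linear interpolation")
    interpolation <- "linear"
  }
  xg <- seq(min(pts$x), max(pts$x), length.out = resolution)
  yg <- seq(min(pts$y), max(pts$y), length.out = resolution)
  if (interpolation == "thin_plate_rbf") {
    n <- nrow(pts)
    d <- as.matrix(stats::dist(pts[, c("x", "y")]))
    P <- cbind(1, pts$x, pts$y)
    A <- rbind(cbind(tps_kernel(d), P), cbind(t(P), matrix(0, 3, 3)))
    coef <- solve(A, c(pts$z, rep(0, 3)))
    w <- coef[seq_len(n)]; a <- coef[n + 1:3]
    eval_tps <- function(px, py) {
      r <- sqrt(outer(px, pts$x, "-")^2 + outer(py, pts$y, "-")^2)
      a[1] + a[2] * px + a[3] * py + drop(tps_kernel(r) %*% w)
    }
    z <- outer(xg, yg, function(gx, gy) eval_tps(gx, gy))
  } else {
    fit <- stats::lm(z ~ x + y, data = pts)
    # collinear inputs leave an aliased coefficient; prediction is still the
    # least-squares affine surface, so the rank-deficiency note is expected
    z <- outer(xg, yg, function(gx, gy)
      suppressWarnings(stats::predict(fit, data.frame(x = gx, y = gy))))
  }
  z <- pmin(max(pts$z), pmax(min(pts$z), z))
  levels <- seq(min(pts$z), max(pts$z), length.out = n_levels + 1L)
  structure(list(x = xg, y = yg, z = z, levels = levels, points = pts,
                 method = interpolation),
            class = "contour_grid")
}

#' Evaluate a fitted contour grid's interpolant at arbitrary points
#'
#' Re-solves nothing: rebuilds the interpolant from the stored source points
#' and evaluates it (used for exactness checks at source locations).
#'
#' @param grid A `contour_grid`.
#' @param x,y Coordinates to evaluate at.
#' @return Interpolated z values (unclipped).
#' @export
evaluate_contour <- function(grid, x, y) {
  pts <- grid$points
  if (grid$method == "thin_plate_rbf") {
    n <- nrow(pts)
    d <- as.matrix(stats::dist(pts[, c("x", "y")]))
    P <- cbind(1, pts$x, pts$y)
    A <- rbind(cbind(tps_kernel(d), P), cbind(t(P), matrix(0, 3, 3)))
    coef <- solve(A, c(pts$z, rep(0, 3)))
    w <- coef[seq_len(n)]; a <- coef[n + 1:3]
    r <- sqrt(outer(x, pts$x, "-")^2 + outer(y, pts$y, "-")^2)
    a[1] + a[2] * x + a[3] * y + drop(tps_kernel(r) %*% w)
  } else {
    fit <- stats::lm(z ~ x + y, data = pts)
    unname(suppressWarnings(stats::predict(fit, data.frame(x = x, y = y))))
  }
}

#' Plot a contour grid
#'
#' Filled-contour rendering of the development-spectrum surface (blue high
#' survival, red low), with the source cells overplotted.
#'
#' @param grid A `contour_grid`.
#' @return A ggplot object.
#' @export
plot_contour <- function(grid) {
  df <- expand.grid(x = grid$x, y = grid$y)
  df$z <- as.vector(grid$z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, z = .data$z)) +
    ggplot2::geom_contour_filled(breaks = grid$levels) +
    ggplot2::scale_fill_manual(
      values = grDevices::hcl.colors(length(grid$levels) - 1L, "RdYlBu"),
      name = "survival") +
    ggplot2::geom_point(data = grid$points,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        inherit.aes = FALSE, size = 0.6) +
    ggplot2::labs(x = "wealth (normalized)", y = "education (normalized)") +
    ggplot2::theme_minimal()
}

#' Equal-count decile classification
#'
#' Ten groups of (as near as possible) equal size over units; ties broken by
#' unit name so the classification is deterministic. Bin sizes differ by at
#' most one.
#'
#' @param values Numeric index values.
#' @param names Unit names (tie-break key).
#' @return Integer deciles 1-10 aligned with the input.
#' @export
decile_bins <- function(values, names) {
  stopifnot(length(values) == length(names))
  ord <- order(values, names)
  rank <- integer(length(values))
  rank[ord] <- seq_along(values)
  as.integer(floor((rank - 1L) * 10L / length(values)) + 1L)
}

normalize_join_key <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Join index results onto unit geometries and export a choropleth
#'
#' Classifies units into equal-count deciles of the index, joins them to
#' GeoJSON features on a case-insensitive punctuation-stripped unit name, and
#' writes a GeoJSON with `index` and `decile` attributes (geometries are
#' passed through untouched). Unmatched names on either side are reported; a
#' join rate below 50% is an error.
#'
#' @param results Unit-level index table with `unit1` and `index`.
#' @param geojson_path Input GeoJSON of unit polygons.
#' @param out_path Output GeoJSON path.
#' @param name_property Feature property holding the unit name.
#' @param figure_path Optional PNG/SVG path for a quick decile map drawn from
#'   the polygon coordinates.
#' @return List `join_report` (unit, matched flag), `unmatched_features`,
#'   `join_rate`, `out_path`, invisibly.
#' @export
choropleth_export <- function(results, geojson_path, out_path,
                              name_property = "name", figure_path = NULL) {
  gj <- jsonlite::fromJSON(geojson_path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  results$decile <- decile_bins(results$index, results$unit1)
  keys <- normalize_join_key(results$unit1)
  feature_names <- vapply(gj$features, function(f)
    as.character(f$properties[[name_property]] %||% NA_character_), "")
  matched_feature <- match(normalize_join_key(feature_names), keys)
  for (i in seq_along(gj$features)) {
    j <- matched_feature[i]
    if (!is.na(j)) {
      gj$features[[i]]$properties$index <- results$index[j]
      gj$features[[i]]$properties$decile <- results$decile[j]
    }
  }
  unit_matched <- keys %in% normalize_join_key(feature_names)
  join_report <- tibble::tibble(unit1 = results$unit1, matched = unit_matched)
  rate <- mean(unit_matched)
  if (rate < 0.5) {
    stop("join rate ", round(100 * rate), "% below 50%; unmatched units: ",
         paste(results$unit1[!unit_matched], collapse = ", "))
  }
  jsonlite::write_json(gj, out_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(figure_path)) {
    poly <- extract_polygons(gj, matched_feature, results)
    p <- ggplot2::ggplot(poly, ggplot2::aes(x = .data$lon, y = .data$lat,
                                            group = .data$ring,
                                            fill = .data$decile)) +
      ggplot2::geom_polygon(color = "grey30", linewidth = 0.1) +
      ggplot2::scale_fill_gradientn(
        colors = grDevices::hcl.colors(10, "RdYlBu"), limits = c(1, 10),
        name = "decile") +
      ggplot2::coord_equal() + ggplot2::theme_void()
    ggplot2::ggsave(figure_path, p, width = 6, height = 6, dpi = 150)
  }
  invisible(list(join_report = join_report,
                 unmatched_features = feature_names[is.na(matched_feature)],
                 join_rate = rate, out_path = out_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flatten Polygon/MultiPolygon rings into a plotting data frame
extract_polygons <- function(gj, matched_feature, results) {
  out <- list(); ring_id <- 0L
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    dec <- if (!is.na(matched_feature[i])) results$decile[matched_feature[i]] else NA
    geom <- f$geometry
    polys <- switch(geom$type, Polygon = list(geom$coordinates),
                    MultiPolygon = geom$coordinates, list())
    for (poly in polys) for (ring in poly) {
      ring_id <- ring_id + 1L
      m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
      out[[ring_id]] <- tibble::tibble(lon = m[, 1], lat = m[, 2],
                                       ring = ring_id, decile = dec)
    }
  }
  dplyr::bind_rows(out)
}
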