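# shared fixtures and independent oracles for the test suite

# small clustered survey reused across files (generated once per run)
sim_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_survey(generator_config(
        n_countries = 2L, units_per_country = 3L, clusters_per_unit = 6L,
        households_per_cluster = 8L, seed = 99L))
    }
    cache
  }
})

# minimal valid child-record tibble; override any field via ...
make_records <- function(n = 3L, ...) {
  out <- tibble::tibble(
    child_id = as.character(seq_len(n)),
    country = "AA",
    survey_year = 2015L,
    unit1 = "North",
    unit2 = NA_character_,
    cluster_id = "c1",
    household_id = paste0("h", seq_len(n)),
    mother_id = paste0("m", seq_len(n)),
    mother_edu_years = 6L,
    mother_age_years = 30L,
    child_sex = "female",
    birth_cmc = 1330L,
    interview_cmc = 1390L,
    alive = "yes",
    age_at_death_months = NA_integer_,
    weight_raw = 1000000L,
    wealth_quintile_provided = NA_integer_
  )
  dots <- list(...)
  for (nm in names(dots)) out[[nm]] <- dots[[nm]]
  out
}

# brute-force oracles, deliberately loop-based and independent of the package
oracle_weighted_mean <- function(x, w) {
  num <- 0; den <- 0
  for (i in seq_along(x)) { num <- num + w[i] * x[i]; den <- den + w[i] }
  num / den
}

oracle_sample_sd <- function(x) {
  m <- sum(x) / length(x)
  acc <- 0
  for (v in x) acc <- acc + (v - m)^2
  sqrt(acc / (length(x) - 1))
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# smallest value whose cumulative normalized weight reaches p (weighted-CDF scan)
oracle_weighted_quantile <- function(x, w, p) {
  ord <- order(x)
  tot <- sum(w); acc <- 0
  for (i in ord) {
    acc <- acc + w[i]
    if (acc / tot >= p - 1e-12) return(x[i])
  }
  x[ord[length(x)]]
}

oracle_quintile_assign <- function(x, w) {
  cuts <- vapply(c(0.2, 0.4, 0.6, 0.8), function(p)
    oracle_weighted_quantile(x, w, p), numeric(1))
  vapply(x, function(v) 1L + sum(v > cuts), integer(1))
}

# Monte-Carlo SE of a weighted cell mean. For child-level independent draws
# (survival) the unit is the child; education and wealth are constant within
# mother/household, so the independent unit is the cluster id passed in.
mc_se <- function(x, w, cluster = seq_along(x)) {
  agg <- rowsum(cbind(w, w * x), cluster)
  W <- agg[, 1]; xc <- agg[, 2] / W
  xb <- sum(w * x) / sum(w)
  sqrt(sum(W^2 * (xc - xb)^2)) / sum(w)
}

# direct dense solve of the thin-plate radial-basis system
oracle_tps_eval <- function(px, py, pz, qx, qy) {
  U <- function(r) ifelse(r > 0, r^2 * log(r), 0)
  n <- length(px)
  K <- outer(seq_len(n), seq_len(n), function(i, j)
    U(sqrt((px[i] - px[j])^2 + (py[i] - py[j])^2)))
  P <- cbind(1, px, py)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  cf <- solve(A, c(pz, 0, 0, 0))
  vapply(seq_along(qx), function(k) {
    r <- sqrt((qx[k] - px)^2 + (qy[k] - py)^2)
    sum(cf[seq_len(n)] * U(r)) + cf[n + 1] + cf[n + 2] * qx[k] + cf[n + 3] * qy[k]
  }, numeric(1))
}
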