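# Fixture builders and independent brute-force oracles shared across tests.

# Minimal valid census profile data.frame; `...` overrides columns.
make_profiles <- function(n, ..., seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- list(
    pct_edu_lt9y = 8, pct_edu_hs_plus = 80, pct_white_collar = 55,
    median_family_income = 55000, income_disparity = 1,
    pct_families_poverty = 8, pct_below_150_poverty = 15,
    pct_unemployed = 5, median_home_value = 150000,
    median_gross_rent = 700, median_mortgage = 1100,
    pct_owner_occupied = 65, pct_no_plumbing = 1, pct_single_parent = 20,
    pct_no_vehicle = 10, pct_no_telephone = 3, pct_crowding = 3)
  df <- as.data.frame(lapply(base, rep, n))
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  cbind(data.frame(unit_id = sprintf("u%03d", seq_len(n))), df)
}

# Random projected-coordinate region: n units scattered in a square of
# side `extent_km`, one aggregate age stratum unless `strata` given.
make_region <- function(n, extent_km = 50, seed = 1, strata = c(all = 1),
                        pop = 1000) {
  set.seed(seed)
  df <- make_profiles(n,
    pct_families_poverty = runif(n, 2, 40),
    median_family_income = runif(n, 25000, 90000),
    pct_unemployed = runif(n, 1, 15))
  df$centroid_x <- runif(n, 0, extent_km) * 1000
  df$centroid_y <- runif(n, 0, extent_km) * 1000
  for (s in names(strata)) {
    df[[paste0("pop_", s)]] <- round(pop * strata[[s]])
  }
  study_region(df, coords = "projected")
}

# O(n^2) count-based percentile: 100 * #{<=} / n.
bf_percentile <- function(scores) {
  vapply(scores, function(s) 100 * sum(scores <= s) / length(scores),
         numeric(1))
}

# Brute-force local calibration: explicit window scan, count-based
# percentile, strict top-percent cut; NA flag below the size floor.
bf_local <- function(region, scores, radius_km, threshold_pct = 15,
                     min_window = 10) {
  d <- pairwise_distance(region)
  n <- n_units(region)
  pct <- numeric(n); flag <- rep(NA, n); size <- integer(n)
  for (i in seq_len(n)) {
    win <- which(d[i, ] <= radius_km)
    size[i] <- length(win)
    pct[i] <- 100 * sum(scores[win] <= scores[i]) / length(win)
    if (length(win) >= min_window) flag[i] <- pct[i] > 100 - threshold_pct
  }
  list(percentile = pct, flag = flag, window_size = size)
}

# Single-period event table from a units x strata count matrix.
events_from_matrix <- function(region, counts, category = "total",
                               year = 2000L) {
  strata <- colnames(region$pop)
  data.frame(
    unit_id = rep(region$unit_id, times = length(strata)),
    age_stratum = rep(strata, each = n_units(region)),
    category = category, year = year,
    count = as.vector(counts), stringsAsFactors = FALSE)
}
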