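test_that("great-circle and Euclidean distances match closed forms", {
  df <- make_profiles(2)
  df$centroid_lon <- c(0, 0); df$centroid_lat <- c(0, 1)
  df$pop_all <- 100
  r <- study_region(df)
  d <- pairwise_distance(r)
  # one degree of latitude on a sphere of radius 6371.0088 km
  expect_equal(d[1, 2], 6371.0088 * pi / 180, tolerance = 1e-6)
  expect_equal(diag(d), setNames(c(0, 0), r$unit_id))
  expect_equal(d, t(d))

  df2 <- make_profiles(2)
  df2$centroid_x <- c(0, 3000); df2$centroid_y <- c(0, 4000)
  df2$pop_all <- 100
  expect_equal(pairwise_distance(study_region(df2))[1, 2], 5) # 3-4-5 triangle

  # identical centroids -> 0 km
  df3 <- df2; df3$centroid_x <- c(10, 10); df3$centroid_y <- c(20, 20)
  expect_equal(pairwise_distance(study_region(df3))[1, 2], 0)
})

test_that("mixed centroid conventions require an explicit choice", {
  df <- make_profiles(2)
  df$centroid_lon <- c(0, 1); df$centroid_lat <- c(0, 1)
  df$centroid_x <- c(0, 1); df$centroid_y <- c(0, 1)
  df$pop_all <- 10
  expect_error(study_region(df), "both")
  expect_silent(r <- study_region(df, coords = "projected"))
  expect_equal(r$coords, "projected")
})

test_that("neighborhoods match a brute-force distance-matrix scan", {
  region <- make_region(50, seed = 21)
  d <- pairwise_distance(region)
  for (u in sample(region$unit_id, 8)) {
    nb <- neighborhood(region, u, 10, dist = d)
    expect_setequal(nb, region$unit_id[d[u, ] <= 10])
  }
  u1 <- region$unit_id[1]
  expect_equal(neighborhood(region, u1, 0), u1)             # radius 0 -> self
  expect_setequal(neighborhood(region, u1, max(d) + 1), region$unit_id)
  expect_error(neighborhood(region, "nope", 10), "unknown unit_id")
  expect_error(neighborhood(region, u1, -1), "non-negative")
})

test_that("every unit is in its own neighborhood and windows nest by radius", {
  region <- make_region(40, seed = 8)
  d <- pairwise_distance(region)
  for (u in sample(region$unit_id, 5)) {
    for (r in c(0, 3, 8, 20)) {
      expect_true(u %in% neighborhood(region, u, r, dist = d))
    }
    expect_true(all(neighborhood(region, u, 5, dist = d) %in%
                      neighborhood(region, u, 12, dist = d)))
  }
})

test_that("regional calibration flags the strict top of the ranking", {
  region <- make_region(20, seed = 2)
  res <- regional_adi(region, setNames(1:20, region$unit_id))
  expect_equal(res$percentile, seq(5, 100, by = 5))
  expect_equal(region$unit_id[res$flag], region$unit_id[18:20])

  # n = 100 unique scores -> exactly 15 flagged at threshold 15
  region100 <- make_region(100, seed = 3)
  res100 <- regional_adi(region100, sample(1:100))
  expect_equal(sum(res100$flag), 15)

  # all-equal scores: everyone at percentile 100, everyone flagged
  res_tie <- regional_adi(region, rep(1, 20))
  expect_true(all(res_tie$percentile == 100))
  expect_true(all(res_tie$flag))
})

test_that("local calibration matches the brute-force window scan", {
  set.seed(31)
  for (k in 1:20) {
    n <- sample(20:200, 1)
    region <- make_region(n, extent_km = sample(c(20, 40, 80), 1), seed = 1000 + k)
    scores <- rnorm(n)
    for (r in c(5, 10)) {
      got <- local_adi(region, scores, r)
      want <- bf_local(region, scores, r)
      expect_equal(got$percentile, want$percentile)
      expect_identical(got$flag, want$flag)
      expect_equal(got$window_size, want$window_size)
    }
  }
})

test_that("radius beyond the region diameter reproduces the regional calibration", {
  for (k in 1:10) {
    n <- sample(15:80, 1)
    region <- make_region(n, seed = 2000 + k)
    scores <- rnorm(n)
    diam <- max(pairwise_distance(region))
    loc <- local_adi(region, scores, diam + 1)
    reg <- regional_adi(region, scores)
    expect_equal(loc$percentile, reg$percentile)
    expect_identical(loc$flag, reg$flag)
  }
})

test_that("rigid translation leaves windows, percentiles and flags unchanged", {
  region <- make_region(60, seed = 17)
  scores <- rnorm(60)
  shifted <- region
  shifted$centroid[, 1] <- shifted$centroid[, 1] + 123456
  shifted$centroid[, 2] <- shifted$centroid[, 2] - 98765
  a <- local_adi(region, scores, 10)
  b <- local_adi(shifted, scores, 10)
  expect_equal(a$percentile, b$percentile)
  expect_identical(a$flag, b$flag)
})

test_that("windows below the size floor yield an indeterminate flag", {
  # 12 units: a tight cluster of 11 and one remote unit
  df <- make_profiles(12, pct_families_poverty = seq(5, 38, 3))
  df$centroid_x <- c(seq(0, 1000, 100), 50000)
  df$centroid_y <- 0
  df$pop_all <- 100
  region <- study_region(df, coords = "projected")
  suppressWarnings(scores <- compute_raw_adi(region$profile))
  res <- local_adi(region, scores, 5, min_window = 10)
  expect_true(is.na(res$flag[12]))       # remote unit: window of 1
  expect_false(anyNA(res$flag[1:11]))    # cluster windows are full-size
  expect_equal(res$percentile[12], 100)  # percentile still reported
  expect_equal(res$window_size[12], 1)
})

test_that("a unit can be flagged locally while unflagged regionally", {
  # two clusters far apart; the 'poor corner' of the affluent cluster is
  # modest regionally but tops its own window
  pov <- c(30, 28, 26, 25, 27, 29, 31, 26, 28, 30,   # poor cluster
           18, 10, 9, 8, 11, 12, 9, 10, 8, 11)       # affluent cluster, one worse
  df <- make_profiles(20, pct_families_poverty = pov)
  df$centroid_x <- c(seq(0, 9000, 1000), seq(100000, 109000, 1000))
  df$centroid_y <- 0
  df$pop_all <- 100
  region <- study_region(df, coords = "projected")
  suppressWarnings(scores <- compute_raw_adi(region$profile))
  reg <- regional_adi(region, scores)
  loc <- local_adi(region, scores, 10, min_window = 10)
  u <- 11 # the locally worst unit of the affluent cluster
  expect_true(loc$flag[u])
  expect_false(reg$flag[u])
})
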