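test_that("crude odds ratios match hand arithmetic", {
  expect_equal(crude_or(c(10, 90, 5, 95))$estimate, (10 * 95) / (90 * 5))
  expect_equal(crude_or(c(7, 7, 7, 7))$estimate, 1)
  # zero cell: Haldane-Anscombe 0.5 on every cell
  expect_equal(crude_or(c(0, 10, 5, 5))$estimate,
               (0.5 * 5.5) / (10.5 * 5.5))
  r <- crude_or(c(10, 90, 5, 95))
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
  expect_error(crude_or(c(1, 2, 3)), "4")
  expect_error(crude_or(c(-1, 2, 3, 4)), "non-negative")
})

test_that("Mantel-Haenszel estimate matches the hand-derived oracle", {
  s <- data.frame(a = c(10, 20), b = c(90, 80), c = c(5, 10), d = c(95, 90))
  r <- mh_or(s)
  expect_equal(r$estimate, (10 * 95 / 200 + 20 * 90 / 200) /
                 (90 * 5 / 200 + 80 * 10 / 200), tolerance = 1e-12)
  expect_equal(r$estimate, 2.2, tolerance = 1e-12)
  expect_equal(r$n_informative_strata, 2)

  # single stratum reduces exactly to the crude OR
  s1 <- data.frame(a = 10, b = 90, c = 5, d = 95)
  expect_identical(mh_or(s1)$estimate, crude_or(c(10, 90, 5, 95))$estimate)

  # replicating a stratum leaves the estimate unchanged
  expect_equal(mh_or(rbind(s1, s1))$estimate, mh_or(s1)$estimate)
})

test_that("Mantel-Haenszel estimate and RBG interval agree with stats::mantelhaen.test", {
  set.seed(12)
  for (k in 1:5) {
    K <- sample(2:6, 1)
    s <- data.frame(a = rpois(K, 15) + 1, b = rpois(K, 80) + 1,
                    c = rpois(K, 10) + 1, d = rpois(K, 90) + 1)
    arr <- array(0, c(2, 2, K))
    for (i in seq_len(K)) arr[, , i] <- rbind(c(s$a[i], s$b[i]), c(s$c[i], s$d[i]))
    mt <- stats::mantelhaen.test(arr, correct = FALSE)
    r <- mh_or(s)
    expect_equal(r$estimate, unname(mt$estimate), tolerance = 1e-12)
    expect_equal(c(r$ci_low, r$ci_high), as.numeric(mt$conf.int),
                 tolerance = 1e-10)
  }
})

test_that("the MH estimate lies between the stratum-specific odds ratios", {
  set.seed(44)
  for (k in 1:10) {
    K <- sample(2:5, 1)
    s <- data.frame(a = rpois(K, 12) + 1, b = rpois(K, 70) + 1,
                    c = rpois(K, 9) + 1, d = rpois(K, 80) + 1)
    ors <- with(s, a * d / (b * c))
    est <- mh_or(s)$estimate
    expect_gte(est, min(ors) - 1e-12)
    expect_lte(est, max(ors) + 1e-12)
  }
})

test_that("exchanging the arms inverts the odds ratio", {
  s <- data.frame(a = c(12, 30), b = c(88, 70), c = c(6, 15), d = c(94, 85))
  r <- mh_or(s)
  r_sw <- mh_or(data.frame(a = s$c, b = s$d, c = s$a, d = s$b))
  expect_equal(r_sw$estimate, 1 / r$estimate, tolerance = 1e-12)
  expect_equal(r_sw$ci_low, 1 / r$ci_high, tolerance = 1e-10)
  expect_equal(r_sw$ci_high, 1 / r$ci_low, tolerance = 1e-10)

  c1 <- crude_or(c(12, 88, 6, 94))
  c2 <- crude_or(c(6, 94, 12, 88))
  expect_equal(c2$estimate, 1 / c1$estimate, tolerance = 1e-12)
})

test_that("scaling every cell by a constant leaves the MH estimate unchanged", {
  s <- data.frame(a = c(10, 20), b = c(90, 80), c = c(5, 10), d = c(95, 90))
  expect_equal(mh_or(s)$estimate,
               mh_or(s * 7)$estimate, tolerance = 1e-12)
})

test_that("degenerate strata follow the error contract", {
  # no stratum with both a*d > 0 and/or b*c > 0: nothing to estimate from
  expect_error(mh_or(data.frame(a = 0, b = 5, c = 0, d = 5)), "informative")
  # denominator sum b*c/n is 0 across strata -> infinite estimate
  r <- mh_or(data.frame(a = c(4, 2), b = c(0, 0), c = c(3, 1), d = c(5, 4)))
  expect_equal(r$estimate, Inf)
  expect_equal(r$ci_high, Inf)
  expect_equal(r$n_informative_strata, 2)
  # numerator sum a*d/n is 0 -> estimate 0
  r0 <- mh_or(data.frame(a = c(0, 3), b = c(5, 4), c = c(3, 2), d = c(2, 0)))
  expect_equal(r0$estimate, 0)
  # a non-informative stratum is skipped and counted
  s <- data.frame(a = c(10, 0), b = c(90, 5), c = c(5, 0), d = c(95, 5))
  expect_equal(mh_or(s)$n_informative_strata, 1)
  expect_equal(mh_or(s)$estimate, mh_or(s[1, ])$estimate)
})

test_that("logistic cross-check agrees with MH on well-behaved tables", {
  s <- data.frame(a = c(30, 60), b = c(270, 240), c = c(15, 30),
                  d = c(285, 270))
  mh <- mh_or(s)
  lg <- logistic_or(s)
  expect_equal(lg$estimate, mh$estimate, tolerance = 0.02)
  expect_equal(lg$method, "logistic")
})

test_that("strata assembly matches direct construction and a brute-force loop", {
  df <- make_profiles(2)
  df$centroid_x <- c(0, 1000); df$centroid_y <- 0
  df$pop_all <- c(100, 100)
  region <- study_region(df, coords = "projected")
  ev <- data.frame(unit_id = c("u001", "u002"), age_stratum = "all",
                   category = "total", year = 2000, count = c(10, 5))
  s <- build_strata(region, c(TRUE, FALSE), ev)
  expect_equal(unlist(s[c("a", "b", "c", "d")], use.names = FALSE),
               c(10, 90, 5, 95))

  # indeterminate flags contribute to neither arm
  s_na <- build_strata(region, c(TRUE, NA), ev)
  expect_equal(unlist(s_na[c("a", "b", "c", "d")], use.names = FALSE),
               c(10, 90, 0, 0))
  expect_equal(attr(s_na, "n_excluded_units"), 1)

  # random region: cells match a per-unit accumulation loop
  region2 <- make_region(30, seed = 77, strata = c(y = 0.6, o = 0.4), pop = 500)
  set.seed(7)
  counts <- matrix(rpois(60, 15), 30, 2, dimnames = dimnames(region2$pop))
  flags <- setNames(sample(c(TRUE, FALSE, NA), 30, replace = TRUE),
                    region2$unit_id)
  s2 <- build_strata(region2, flags, events_from_matrix(region2, counts))
  for (j in seq_along(colnames(region2$pop))) {
    st <- colnames(region2$pop)[j]
    a <- b <- cc <- d <- 0
    for (i in 1:30) {
      if (is.na(flags[i])) next
      if (flags[i]) {
        a <- a + counts[i, j]; b <- b + region2$pop[i, j] - counts[i, j]
      } else {
        cc <- cc + counts[i, j]; d <- d + region2$pop[i, j] - counts[i, j]
      }
    }
    expect_equal(unlist(s2[s2$stratum == st, c("a", "b", "c", "d")],
                        use.names = FALSE), c(a, b, cc, d))
  }
})

test_that("fractional averaged counts are rounded half-up and capped at population", {
  df <- make_profiles(2)
  df$centroid_x <- c(0, 1000); df$centroid_y <- 0
  df$pop_all <- c(10, 100)
  region <- study_region(df, coords = "projected")
  ev <- data.frame(unit_id = c("u001", "u002"), age_stratum = "all",
                   category = "total", year = NA_integer_, count = c(12.5, 4.5))
  expect_warning(s <- build_strata(region, c(TRUE, FALSE), ev), "capped")
  expect_equal(s$a, 10)  # 12.5 -> 13, capped at pop 10
  expect_equal(s$c, 5)   # 4.5 rounds half-up to 5
})

test_that("identical flags across scales give identical odds ratios", {
  region <- make_region(40, seed = 55, pop = 2000)
  suppressWarnings(raw <- compute_raw_adi(region$profile))
  set.seed(3)
  counts <- matrix(rbinom(40, region$pop, 0.1), ncol = 1,
                   dimnames = dimnames(region$pop))
  ev <- events_from_matrix(region, counts)
  diam <- max(pairwise_distance(region))
  tab <- compare_scales(region, raw, ev, radii = c(diam + 1, diam + 2))
  expect_equal(tab$estimate[1], tab$estimate[2], tolerance = 1e-12)
  expect_equal(tab$estimate[1], tab$estimate[tab$scale == "regional"],
               tolerance = 1e-12)
})
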