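test_that("ICD-9 codes classify by inclusive 3-digit root ranges", {
  expect_equal(classify_icd9("493.20"), "respiratory")
  expect_equal(classify_icd9(c("460", "519", "520", "459.9")),
               c("respiratory", "respiratory", NA, "circulatory"))
  expect_equal(classify_icd9(c("390", "459", "389")),
               c("circulatory", "circulatory", NA))
  expect_equal(classify_icd9(c("290", "319", "289", "320")),
               c("mental", "mental", NA, NA))
})

test_that("the named categories partition: no code maps to two of them", {
  codes <- sprintf("%03d", 1:999)
  cats <- classify_icd9(codes)
  in_resp <- !is.na(cats) & cats == "respiratory"
  in_circ <- !is.na(cats) & cats == "circulatory"
  in_ment <- !is.na(cats) & cats == "mental"
  expect_true(all(in_resp + in_circ + in_ment <= 1))
  expect_equal(sum(in_resp), 60)
  expect_equal(sum(in_circ), 70)
  expect_equal(sum(in_ment), 30)
})

test_that("V/E and unparseable codes fall outside all categories by default", {
  codes <- c("V27.0", "E880.9", "garbage", "49")
  expect_true(all(is.na(classify_icd9(codes))))
  expect_equal(icd9_in_total(codes), rep(FALSE, 4))
  expect_equal(icd9_in_total(codes, include_ve_in_total = TRUE),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_true(icd9_in_total("493.20"))
})

test_that("multi-year averaging takes the arithmetic mean with absent years as 0", {
  ev <- data.frame(unit_id = "u1", age_stratum = "all", category = "total",
                   year = c(1999, 2000, 2001), count = c(3, 6, 3))
  avg <- average_years(ev, 1999:2001)
  expect_equal(avg$count, 4)

  one <- average_years(ev[2, ], 2000)
  expect_equal(one$count, 6) # single year is the identity

  # unit missing a year: counted as 0 and warned about
  ev2 <- rbind(ev, data.frame(unit_id = "u2", age_stratum = "all",
                              category = "total", year = 1999, count = 9))
  expect_warning(avg2 <- average_years(ev2, 1999:2001), "absent")
  expect_equal(avg2$count[avg2$unit_id == "u2"], 3)
  expect_equal(avg2$count[avg2$unit_id == "u1"], 4)

  expect_error(average_years(ev, integer(0)), "at least one year")
})

test_that("indirect standardization reproduces hand-computed SMRs", {
  df <- make_profiles(2)
  df$centroid_x <- c(0, 1000); df$centroid_y <- 0
  df$pop_young <- c(1000, 500); df$pop_old <- c(100, 50)
  region <- study_region(df, coords = "projected")
  std <- standard_population(c(young = 0.01, old = 0.10), crude_rate = 0.02)

  ev <- data.frame(unit_id = "u001", age_stratum = c("young", "old"),
                   category = "total", year = 2000, count = c(25, 5))
  adj <- indirect_adjust(region, ev, std)
  # expected for u001 = 0.01*1000 + 0.10*100 = 20; observed 30 -> SMR 1.5
  expect_equal(adj$expected[1], 20)
  expect_equal(adj$smr[1], 1.5)
  expect_equal(adj$adjusted_rate[1], 1.5 * 0.02)
  # u002 has no events: observed 0, SMR 0
  expect_equal(adj$observed[2], 0)
  expect_equal(adj$smr[2], 0)
})

test_that("units whose stratum rates equal the standard have SMR exactly 1", {
  region <- make_region(6, seed = 4, strata = c(young = 0.7, old = 0.3),
                        pop = 1000)
  std <- standard_population(c(young = 0.05, old = 0.2), crude_rate = 0.095)
  counts <- sweep(region$pop, 2, std$rates[colnames(region$pop)], "*")
  adj <- indirect_adjust(region, events_from_matrix(region, counts), std)
  expect_equal(adj$smr, rep(1, 6), tolerance = 1e-14)
  expect_equal(adj$adjusted_rate, rep(std$crude_rate, 6), tolerance = 1e-14)
})

test_that("SMR is invariant to scaling populations and counts together", {
  region <- make_region(4, seed = 9, strata = c(young = 0.6, old = 0.4),
                        pop = 800)
  std <- standard_population(c(young = 0.02, old = 0.12), crude_rate = 0.06)
  set.seed(1)
  counts <- matrix(rpois(8, 20), 4, 2, dimnames = dimnames(region$pop))
  adj1 <- indirect_adjust(region, events_from_matrix(region, counts), std)

  region2 <- region
  region2$pop <- region$pop * 3
  adj2 <- indirect_adjust(region2, events_from_matrix(region2, counts * 3), std)
  expect_equal(adj1$smr, adj2$smr, tolerance = 1e-12)
})

test_that("degenerate expected counts are handled per contract", {
  df <- make_profiles(2)
  df$centroid_x <- c(0, 1000); df$centroid_y <- 0
  df$pop_all <- c(0, 100)
  region <- study_region(df, coords = "projected")
  std <- standard_population(c(all = 0.1), crude_rate = 0.1)
  # expected 0, observed 0 -> SMR missing
  ev0 <- data.frame(unit_id = "u002", age_stratum = "all", category = "total",
                    year = 2000, count = 5)
  adj <- indirect_adjust(region, ev0, std)
  expect_true(is.na(adj$smr[1]))
  # expected 0 with observed > 0 -> error
  ev_bad <- data.frame(unit_id = "u001", age_stratum = "all",
                       category = "total", year = 2000, count = 5)
  expect_error(indirect_adjust(region, ev_bad, std), "expected")
})
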