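# QOF revenue engine: achievement, threshold ramp, revenue, price shock.

test_that("achievement rate is the eligible-patient proportion", {
  expect_identical(achievement_rate(20, 50), 0.4)
  expect_identical(achievement_rate(50, 50), 1)
  expect_identical(achievement_rate(0, 50), 0)
  expect_error(achievement_rate(10, 0), "zero denominator")
  expect_error(achievement_rate(60, 50), "numerator <= denominator")
})

test_that("points ramp linearly between the thresholds with two kinks", {
  ind <- qof_indicator("X", max_points = 10,
                       lower_threshold = 0.40, upper_threshold = 0.90)
  expect_identical(points_earned(0.40, ind), 0)   # at-or-below lower: none
  expect_identical(points_earned(0.39, ind), 0)
  expect_identical(points_earned(0.90, ind), 10)  # at-or-above upper: full
  expect_identical(points_earned(1.00, ind), 10)
  expect_equal(points_earned(0.65, ind), 5)       # midpoint of the ramp

  # brute-force linearity/monotonicity on a fine grid
  A <- seq(0, 1, by = 1e-3)
  pts <- points_earned(A, ind)
  expect_true(all(diff(pts) >= 0))
  inside <- A > 0.40 & A < 0.90
  slope <- 10 / 0.5
  expect_equal(pts[inside], (A[inside] - 0.40) * slope, tolerance = 1e-12)
  # exactly two kinks in the second difference
  kinks <- which(abs(diff(pts, differences = 2)) > 1e-9)
  expect_length(kinks, 2L)
})

test_that("revenue sums threshold-ramped points at the price per point", {
  reg <- fixture_registry(price = 100)
  recs <- fixture_records()
  # hand-derived: A = .65 -> 5 pts; A = .5 -> 2 pts; A = .7 -> 6 pts
  rev <- practice_revenue(recs, reg)
  expect_equal(unname(rev$total["P1"]), (5 + 2 + 6) * 100)
  expect_equal(sum(rev$breakdown$revenue), unname(rev$total["P1"]))

  # one maximum point at the upper threshold under the 2004 price is 76 GBP
  reg04 <- qof_registry(2004, list(
    qof_indicator("I1", max_points = 1, lower_threshold = 0.4,
                  upper_threshold = 0.9)), price_per_point = 76)
  one <- data.frame(practice_id = "P1", indicator_id = "I1",
                    numerator = 90, denominator = 100)
  expect_equal(unname(practice_revenue(one, reg04)$total["P1"]), 76)

  # revenue is homogeneous of degree one in the price
  reg2 <- fixture_registry(price = 250)
  expect_equal(unname(practice_revenue(recs, reg2)$total["P1"]),
               2.5 * unname(rev$total["P1"]))

  # everything at or below the lower thresholds earns nothing
  low <- transform(recs, numerator = c(40, 25, 16))
  expect_equal(unname(practice_revenue(low, reg)$total["P1"]), 0)

  bad <- transform(recs, indicator_id = c("A1", "A2", "ZZ"))
  expect_error(practice_revenue(bad, reg), "ZZ")
})

test_that("proportion of total points spans 0-100 and matches hand ratio", {
  reg <- fixture_registry()
  full <- data.frame(practice_id = "P1", indicator_id = c("A1", "A2", "A3"),
                     numerator = c(95, 80, 75), denominator = 100)
  expect_equal(unname(proportion_total_points(full, reg)["P1"]), 100)
  none <- transform(full, numerator = c(10, 10, 10))
  expect_equal(unname(proportion_total_points(none, reg)["P1"]), 0)
  mixed <- fixture_records()  # 5 + 2 + 6 of 10 + 4 + 6 points
  expect_equal(unname(proportion_total_points(mixed, reg)["P1"]),
               100 * 13 / 20)
})

test_that("price shock is zero for identical registries, negative for a
           threshold-only tightening, and matches a hand computation", {
  reg05 <- fixture_registry(price = 125)
  recs <- data.frame(practice_id = "P1", indicator_id = c("A1", "A2", "A3"),
                     numerator = c(80, 50, 28), denominator = c(100, 100, 40))
  same <- price_shock(recs, reg05, reg05, subset = c("A1", "A2"))
  expect_identical(same$shock_money, 0)
  expect_identical(same$shock_pct, 0)

  # raise A1's upper threshold 0.70 -> 0.90 while A = 0.8:
  # before: (0.8-0.4)/(0.3) capped -> full 10 pts; after: (0.8-0.4)/0.5 = 8 pts
  reg05b <- qof_registry(2005, list(
    qof_indicator("A1", "CVD", 10, 0.40, 0.70),
    qof_indicator("A2", "general", 4, 0.25, 0.75),
    qof_indicator("A3", "general", 6, 0.40, 0.70)), price_per_point = 125)
  reg06 <- qof_registry(2006, list(
    qof_indicator("A1", "CVD", 10, 0.40, 0.90),
    qof_indicator("A2", "general", 4, 0.25, 0.75),
    qof_indicator("A3", "general", 6, 0.40, 0.70)), price_per_point = 125)
  sh <- price_shock(recs, reg05b, reg06, subset = "A1")
  expect_lt(sh$shock_money, 0)
  expect_equal(sh$shock_money, (8 - 10) * 125)
  # total 2005 revenue: 10 + 2 + 6 points at 125 each
  expect_equal(sh$shock_pct, 100 * (8 - 10) * 125 / ((10 + 2 + 6) * 125))

  # performance above both years' upper thresholds: no shock
  high <- transform(recs, numerator = c(95, 50, 28))
  expect_identical(price_shock(high, reg05b, reg06, subset = "A1")$shock_money,
                   0)
  expect_error(price_shock(recs, reg05b, reg06, subset = "NOPE"), "NOPE")
})

test_that("threshold-only tightening gives non-positive shocks everywhere", {
  reg05 <- default_registry(2005)
  reg06 <- default_registry(2006)
  cvd <- attr(reg05, "cvd_subset")
  set.seed(31)
  recs <- expand.grid(practice_id = sprintf("P%02d", 1:20),
                      indicator_id = names(reg05$indicators),
                      stringsAsFactors = FALSE)
  recs$denominator <- 80L
  recs$numerator <- rbinom(nrow(recs), 80L, runif(nrow(recs), 0.3, 0.99))
  sh <- price_shock(recs, reg05, reg06, subset = cvd)
  expect_true(all(sh$shock_money <= 0))
  expect_true(all(sh$shock_pct <= 0))
})

test_that("the default registries carry the scheme's printed constants", {
  reg04 <- default_registry(2004)
  reg05 <- default_registry(2005)
  expect_length(reg04$indicators, 146L)
  expect_identical(reg04$price_per_point, 76)
  expect_identical(reg05$price_per_point, 125)
  lows <- vapply(reg04$indicators, `[[`, 0, "lower_threshold")
  expect_true(all(lows == 0.40))
  expect_length(attr(reg04, "cvd_subset"), 4L)
})

test_that("registries round-trip through JSON", {
  reg <- fixture_registry()
  path <- tempfile(fileext = ".json")
  write_registry_json(reg, path)
  back <- read_registry_json(path)
  expect_identical(back$year, reg$year)
  expect_identical(back$price_per_point, reg$price_per_point)
  expect_identical(lapply(back$indicators, unclass),
                   lapply(reg$indicators, unclass))
  unlink(path)
})
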