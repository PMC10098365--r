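test_that("percentile times interpolate linearly between scoring nodes", {
  rec <- data.frame(dish = "d1", temperature_C = 24, time_d = c(2, 3, 4),
                    tr_count = c(12, 18, 18), er_count = c(12, 18, 18),
                    dish_size = 30)
  pt <- interpolatePercentileTimes(rec, c(40, 50, 60, 70))
  expect_equal(pt$time[pt$percentile == 40], 2)     # exact node (40% at 2 d)
  expect_equal(pt$time[pt$percentile == 50], 2.5)   # between 40% and 60%
  expect_equal(pt$time[pt$percentile == 60], 3)     # exact node
  expect_false(pt$reached[pt$percentile == 70])     # final cumulative is 60%
  expect_error(interpolatePercentileTimes(rec[0, ], 50), "empty")
})

test_that("percentile times are monotone in the percentile at fixed temperature", {
  p <- blackParams()
  rec <- simulateExperiment(experimentDesign(22, scoringTimes = 1:45, rngSeed = 9), p)
  pt <- interpolatePercentileTimes(rec, seq(5, 50, 5))
  tt <- pt$time[pt$reached]
  expect_true(!is.unsorted(tt))
})

test_that("splitRegimes applies the argmax rule with the peak in both regimes", {
  g <- expand.grid(temperature = c(12, 16, 20, 24, 28, 32), percentile = 50)
  g$gr <- c(1, 2, 3, 4, 3, 2) / 10
  sp <- splitRegimes(g)
  expect_equal(sp$peak, 24)
  expect_equal(sp$sub, c(12, 16, 20, 24))
  expect_equal(sp$supra, c(24, 28, 32))
  gUp <- g; gUp$gr <- g$temperature / 100          # monotone increasing
  expect_warning(spUp <- splitRegimes(gUp), "monotone increasing")
  expect_lte(length(spUp$supra), 1)
  expect_error(splitRegimes(g[g$temperature %in% c(12, 16), ]), "fewer than 3")
})

test_that("sub-optimal fit exactly recovers a noiseless line and scales correctly", {
  g <- expand.grid(temperature = c(12, 16, 20, 24), percentile = 50)
  g$gr <- (g$temperature - 8) / 144
  f <- fitSuboptimal(g)
  expect_equal(attr(f, "tBase"), 8, tolerance = 1e-9)
  expect_equal(f$theta, 144, tolerance = 1e-9)
  # doubling all rates halves theta and keeps the base temperature
  g2 <- g; g2$gr <- 2 * g$gr
  f2 <- fitSuboptimal(g2)
  expect_equal(f2$theta, 72, tolerance = 1e-9)
  expect_equal(attr(f2, "tBase"), 8, tolerance = 1e-9)
  gFlat <- g; gFlat$gr <- 0.1
  expect_error(fitSuboptimal(gFlat), "misassignment")
})

test_that("supra-optimal fit exactly recovers ceiling and thermal constant", {
  g <- expand.grid(temperature = c(26, 28, 30, 32), percentile = 50)
  g$gr <- (35 - g$temperature) / 99
  f <- fitSupraoptimal(g)
  expect_equal(f$tc, 35, tolerance = 1e-9)
  expect_equal(attr(f, "thetaWarm"), 99, tolerance = 1e-9)
  # three exact points equal the hand-computed OLS line
  g3 <- g[1:3, ]
  f3 <- fitSupraoptimal(g3)
  expect_equal(f3$slope, -1 / 99, tolerance = 1e-12)
  gPos <- g; gPos$gr <- rev(g$gr)
  expect_error(fitSupraoptimal(gPos), "misassignment")
})

test_that("probit fit of threshold values recovers median and SD", {
  g <- c(20, 35, 50, 65, 80)
  v <- 144 + 30 * qnorm(g / 100)
  d <- fitThresholdDistribution(v, g, gRef = 100)
  expect_equal(d$median, 144, tolerance = 1e-9)
  expect_equal(d$sd, 30, tolerance = 1e-9)
  # symmetric values around 140 -> median 140
  d2 <- fitThresholdDistribution(c(130, 140, 150), c(30, 50, 70), gRef = 100)
  expect_equal(d2$median, 140, tolerance = 1e-9)
  d3 <- fitThresholdDistribution(c(5, 5, 5), c(30, 50, 70), gRef = 100)
  expect_equal(d3$sd, 0, tolerance = 1e-12)
  expect_error(fitThresholdDistribution(5, 50, gRef = 100), "2 distinct")
})

test_that("fitting noiseless closed-form curves recovers the generating parameters exactly", {
  p <- blackParams(pViable = 0.6, erLag50 = 0)
  rec <- noiselessRecords(p, c(13, 16, 19, 22, 25, 28, 31))
  fit <- fitThermalTime(rec)
  expect_equal(tBase(fit), 8, tolerance = 1e-6)
  expect_equal(thetaCold50(fit), 144, tolerance = 1e-6)
  expect_equal(sigmaTheta(fit), 30, tolerance = 1e-6)
  expect_equal(tc50(fit), 35, tolerance = 1e-6)
  expect_equal(sigmaTc(fit), 2, tolerance = 1e-6)
  expect_equal(thetaWarm(fit), 99, tolerance = 1e-6)
  expect_equal(tOpt(fit), 24, tolerance = 1e-6)
})

test_that("recovered thresholds are ordered and bias shrinks with sample size", {
  p <- blackParams(pViable = 0.6)
  run <- function(seedsPerDish, nDishes, i) {
    d <- experimentDesign(fixtureTemperatures("black_AR_1"),
                          nDishes = nDishes, seedsPerDish = seedsPerDish,
                          scoringTimes = 1:45, rngSeed = 1 + seedStride * i)
    suppressWarnings(fitThermalTime(simulateExperiment(d, p)))
  }
  small <- sapply(1:8, function(i) tBase(run(30, 3, i)))
  big <- sapply(1:8, function(i) tBase(run(150, 6, i)))
  expect_lte(abs(median(big) - 8), abs(median(small) - 8) + 0.35)
  f <- run(150, 6, 1)
  # theta_cold(g) monotone in g under comonotonic generation
  expect_true(!is.unsorted(f@subDiagnostics$theta))
  expect_true(tBase(f) < tOpt(f) && tOpt(f) < tc50(f))
})

test_that("degenerate inputs fail informatively", {
  p <- blackParams(pViable = 0)
  rec <- simulateExperiment(
    experimentDesign(c(13, 17, 21, 25), scoringTimes = 1:14, rngSeed = 2), p)
  expect_error(fitThermalTime(rec), "percentiles")
  p2 <- blackParams()
  recNarrow <- simulateExperiment(
    experimentDesign(c(20, 24), scoringTimes = 1:14, rngSeed = 2), p2)
  expect_error(fitThermalTime(recNarrow), "4 temperatures")
})
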