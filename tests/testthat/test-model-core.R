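test_that("germination rate is piecewise linear and vanishes at the cardinal temperatures", {
  p <- blackParams(pViable = 1)
  s <- list(thetaCold = 144, tc = 35, viable = TRUE)
  expect_equal(germinationRate(8, s, p), 0)          # base temperature
  expect_equal(germinationRate(24, s, p), 16 / 144)  # (24-8)/144 = 0.1111
  expect_equal(germinationRate(35, s, p), 0)         # ceiling
  expect_error(germinationRate(NaN, s, p), "finite")
  expect_error(germinationRate(24, list(thetaCold = 144, tc = 35, viable = FALSE), p),
               "viable")
  # continuity across a fine grid, never negative
  grid <- seq(0, 45, by = 0.01)
  r <- germinationRate(grid, s, p)
  expect_true(all(r >= 0))
  expect_lt(max(abs(diff(r))), 0.02 * 0.011)  # bounded slope => continuous
})

test_that("time to germination is the reciprocal rate with a non-germinating marker", {
  p <- blackParams(pViable = 1)
  s <- list(thetaCold = 144, tc = 35, viable = TRUE)
  expect_equal(timeToGermination(24, s, p), 9)
  expect_equal(timeToGermination(7, s, p), Inf)   # below base
  s2 <- list(thetaCold = 144, tc = 35, viable = TRUE)
  p2 <- seedPopulationParams(8, 144, 30, 35, 2, thetaWarm = 99)
  expect_equal(timeToGermination(30, list(thetaCold = 1e-9, tc = 35, viable = TRUE), p2),
               99 / 5)                            # supra-optimal branch: 19.8 d
  expect_equal(timeToGermination(24, list(thetaCold = 144, tc = 35, viable = FALSE), p),
               Inf)
})

test_that("estimateTopt solves the two-line intersection", {
  expect_equal(estimateTopt(8, 144, 35, 99), 24)
  expect_equal(estimateTopt(5, 120, 29, 120), 17)        # symmetric: midpoint
  expect_equal(estimateTopt(10.5, 120, 33.5, 120), 22)
  t <- estimateTopt(8, 144, 35, 99)
  expect_true(t > 8 && t < 35)
  expect_error(estimateTopt(8, 144, 7, 99), "degenerate")
  expect_error(estimateTopt(8, -1, 35, 99), "> 0")
})

test_that("predictCumulative matches the closed form and its limits", {
  p <- blackParams(pViable = 1, erLag50 = 0)
  expect_equal(predictCumulative(5, c(1, 10, 100), p), c(0, 0, 0))  # T <= tBase
  expect_equal(predictCumulative(24, 9, p), pnorm(0))               # 0.5 at t50
  expect_equal(predictCumulative(24, 1e6, p), 1, tolerance = 1e-6)  # -> pViable
  p6 <- blackParams(pViable = 0.6)
  expect_equal(predictCumulative(24, 1e6, p6), 0.6, tolerance = 1e-5)
  # sigma = 0 collapses to a step, not an error
  p0 <- seedPopulationParams(8, 144, 0, 35, 0, 99, pViable = 1)
  expect_equal(predictCumulative(24, c(8.99, 9.01), p0), c(0, 1))
})

test_that("predictCumulative is monotone in time, pViable and sub-optimal temperature", {
  p <- blackParams(pViable = 0.8)
  tms <- seq(0, 40, by = 0.5)
  for (T in c(12, 18, 24, 30)) {
    f <- predictCumulative(T, tms, p)
    expect_true(!is.unsorted(f))
    expect_true(all(f <= p@pViable + 1e-12))
  }
  lo <- blackParams(pViable = 0.3); hi <- blackParams(pViable = 0.9)
  expect_true(all(predictCumulative(20, tms, lo) <= predictCumulative(20, tms, hi) + 1e-12))
  # sub-optimal: warmer is faster (up to far-tail ceiling mass < 1e-4,
  # i.e. below a tenth of a seed in the largest assays simulated here)
  expect_true(all(predictCumulative(14, tms, p) <= predictCumulative(18, tms, p) + 1e-4))
})

test_that("predictCumulative agrees with the Monte-Carlo simulator", {
  p <- blackParams(pViable = 0.6, erLag50 = 0)
  for (T in c(24, 30)) {
    d <- experimentDesign(T, nDishes = 4, seedsPerDish = 2500,
                          scoringTimes = 1:30, rngSeed = 99)
    rec <- simulateExperiment(d, p)
    curve <- aggregate(cbind(tr_count, dish_size) ~ time_d, rec, sum)
    emp <- curve$tr_count / curve$dish_size
    expect_equal(emp, predictCumulative(T, curve$time_d, p), tolerance = 0.02)
  }
})

test_that("drawSeeds produces comonotonic, physically valid thresholds", {
  set.seed(42)
  p <- blackParams(pViable = 0.6)
  s <- drawSeeds(5000, p)
  expect_true(all(s$thetaCold > 0))
  expect_true(all(s$tc > p@tBase))
  # fast seeds (low theta) have high ceilings
  expect_true(cor(s$thetaCold, s$tc) < -0.99)
  expect_equal(mean(s$viable), 0.6, tolerance = 0.03)
  expect_equal(median(s$thetaCold), 144, tolerance = 2)
})

test_that("parameter validity catches inconsistent populations", {
  expect_error(seedPopulationParams(35, 144, 30, 8, 2, 99), "tBase")
  expect_error(seedPopulationParams(8, -1, 30, 35, 2, 99), "thetaCold50")
  expect_error(seedPopulationParams(8, 144, 30, 35, 2, 99, pViable = 1.2), "pViable")
})
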