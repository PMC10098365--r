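test_that("simulated dishes respect the count invariants", {
  p <- blackParams()
  d <- experimentDesign(c(16, 24, 30), nDishes = 3, seedsPerDish = 30,
                        scoringTimes = 1:20, rngSeed = 5)
  rec <- simulateExperiment(d, p)
  expect_silent(validateGerminationRecords(rec))
  expect_true(all(rec$er_count <= rec$tr_count))
  expect_true(all(rec$tr_count <= rec$dish_size))
  expect_equal(nrow(rec), 3 * 3 * 20)
})

test_that("identical designs and seeds give bit-identical datasets", {
  p <- blackParams()
  d <- experimentDesign(c(16, 24), rngSeed = 11, scoringTimes = 1:14)
  expect_identical(simulateExperiment(d, p), simulateExperiment(d, p))
  d2 <- experimentDesign(c(16, 24), rngSeed = 12, scoringTimes = 1:14)
  expect_false(identical(simulateExperiment(d, p), simulateExperiment(d2, p)))
})

test_that("zero viability yields all-zero counts", {
  p <- blackParams(pViable = 0)
  d <- experimentDesign(24, rngSeed = 3)
  rec <- simulateExperiment(d, p)
  expect_true(all(rec$tr_count == 0) && all(rec$er_count == 0))
})

test_that("final germinated fraction converges to pViable at sub-optimal temperature", {
  p <- blackParams(pViable = 0.6)
  d <- experimentDesign(20, nDishes = 1, seedsPerDish = 5000,
                        scoringTimes = 1:60, rngSeed = 21)
  rec <- simulateExperiment(d, p)
  phat <- rec$er_count[nrow(rec)] / 5000
  ci <- 3 * sqrt(0.6 * 0.4 / 5000)
  expect_lt(abs(phat - 0.6), ci)
})

test_that("ABA delays endosperm rupture without touching testa rupture (matched seeds)", {
  st <- dormancyState(1, 0, 0)
  base <- blackParams(pViable = 1)
  ctrl <- applyTreatment(st, treatmentFlags(), base)
  aba <- applyTreatment(st, treatmentFlags(abaConc = 10), base)
  d <- experimentDesign(24, nDishes = 3, seedsPerDish = 50,
                        scoringTimes = 1:30, rngSeed = 77)
  r0 <- simulateExperiment(d, ctrl)
  r1 <- simulateExperiment(d, aba)
  expect_identical(r0$tr_count, r1$tr_count)      # TR stream untouched
  expect_false(identical(r0$er_count, r1$er_count))
  expect_true(all(r1$er_count <= r0$er_count))    # ER only ever delayed
})

test_that("treatment rules reproduce the dormancy-release ladder of viable fractions", {
  st <- dormancyStateFixture("FH_black_1")
  base <- blackParams(pViable = 1)
  pv <- function(...) pViable(applyTreatment(st, treatmentFlags(...), base))
  expect_equal(pv(light = FALSE), 0)                       # dark: no germination
  expect_equal(pv(), fNd(st))                              # water control
  expect_equal(pv(afterRipened = TRUE), fNd(st) + fNpd(st))
  expect_equal(pv(ga = TRUE), fNd(st) + fNpd(st))
  expect_equal(pv(fluridone = TRUE), fNd(st))              # fluridone alone: no-op
  expect_gt(pv(ga = TRUE, fluridone = TRUE), pv(ga = TRUE))
  expect_equal(pv(ga = TRUE, ethylene = TRUE, nitrate = TRUE), 1)  # full release
  expect_gt(pv(ga = TRUE, ethylene = TRUE, nitrate = TRUE), 0.90)
  expect_equal(pv(scarified = TRUE), treatmentRulesFixture()$scarifiedFraction)
})

test_that("germination records round-trip through the CSV writer and reader", {
  p <- blackParams()
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  # empty, single-dish and multi-temperature datasets
  sets <- list(
    simulateExperiment(experimentDesign(24, nDishes = 1, rngSeed = 1), p)[0, ],
    simulateExperiment(experimentDesign(24, nDishes = 1, rngSeed = 1), p),
    simulateExperiment(experimentDesign(c(16, 24, 30), rngSeed = 2), p))
  for (rec in sets) {
    if (nrow(rec) == 0) {
      writeGerminationCsv(rec, tmp)
      expect_warning(back <- readGerminationCsv(tmp), "no data rows")
      expect_equal(nrow(back), 0)
    } else {
      writeGerminationCsv(rec, tmp)
      back <- readGerminationCsv(tmp)
      rownames(rec) <- NULL
      expect_equal(back, rec)
    }
  }
})

test_that("design validation rejects degenerate setups", {
  expect_error(experimentDesign(numeric(0), rngSeed = 1), "empty temperature")
  expect_error(experimentDesign(24, scoringTimes = c(2, 1), rngSeed = 1),
               "strictly increasing")
  expect_error(experimentDesign(24, nDishes = 0, rngSeed = 1), "positive")
})
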