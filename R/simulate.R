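#' Construct an experiment design
#'
#' @param temperatures imbibition temperatures (degC).
#' @param nDishes replicate dishes per temperature (default 3).
#' @param seedsPerDish seeds sown per dish (default 30).
#' @param scoringTimes strictly increasing scoring times in days (default
#'   daily scoring, days 1 to 14).
#' @param treatment a [TreatmentFlags-class] object.
#' @param rngSeed integer seed; identical seeds give bit-identical datasets.
#' @return a validated [ExperimentDesign-class] object.
#' @examples
#' experimentDesign(temperatures = c(16, 20, 24), rngSeed = 1)
#' @export
experimentDesign <- function(temperatures, nDishes = 3, seedsPerDish = 30,
                             scoringTimes = 1:14, treatment = treatmentFlags(),
                             rngSeed = 1) {
  if (length(temperatures) == 0L) stop("design error: empty temperature list")
  new("ExperimentDesign", temperatures = as.numeric(temperatures),
      nDishes = as.integer(nDishes), seedsPerDish = as.integer(seedsPerDish),
      scoringTimes = as.numeric(scoringTimes), treatment = treatment,
      rngSeed = as.integer(rngSeed))
}

# One root seed; per (temperature, dish) substreams at fixed offsets so
# adding dishes or temperatures never reshuffles earlier draws.
.dishSeed <- function(root, tempIndex, dish) {
  (root + 1000003L * tempIndex + 7919L * dish) %% .Machine$integer.max
}

#' Simulate replicate petri-dish germination experiments
#'
#' Monte-Carlo realization of the population thermal-time model.  Per seed:
#' viability is Bernoulli(`pViable`), thresholds come from [drawSeeds()],
#' the testa-rupture (TR) time is [timeToGermination()], and the
#' endosperm-rupture (ER) time adds a lognormal lag with median
#' `erLag50 * lagMultiplierAba`.  Events are recorded at the first scoring
#' time at or after the event (daily scoring bins, closed on the right).
#' Exogenous ABA therefore shifts ER only; under a fixed seed the TR
#' time-course is identical at any ABA dose.
#'
#' @param design an [ExperimentDesign-class] object.
#' @param params a [SeedPopulationParams-class] object (typically from
#'   [applyTreatment()] or [seedParamSet()]).
#' @param treatmentId label written to the `treatment_id` column.
#' @return a data.frame of germination records with columns `dish`,
#'   `temperature_C`, `time_d`, `tr_count`, `er_count`, `dish_size`,
#'   `treatment_id`; cumulative counts, `er_count <= tr_count <= dish_size`.
#' @examples
#' p <- seedPopulationParams(8, 144, 30, 35, 2, 99, pViable = 0.6)
#' d <- experimentDesign(24, rngSeed = 7)
#' head(simulateExperiment(d, p))
#' @export
simulateExperiment <- function(design, params, treatmentId = "none") {
  stopifnot(is(design, "ExperimentDesign"), is(params, "SeedPopulationParams"))
  validObject(design); validObject(params)
  if (length(design@temperatures) == 0L) stop("design error: empty temperature list")

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  })

  lagMedian <- params@erLag50 * params@lagMultiplierAba
  res <- vector("list", length(design@temperatures) * design@nDishes)
  k <- 0L
  for (ti in seq_along(design@temperatures)) {
    temp <- design@temperatures[ti]
    for (dish in seq_len(design@nDishes)) {
      set.seed(.dishSeed(design@rngSeed, ti, dish))
      seeds <- drawSeeds(design@seedsPerDish, params)
      # lag drawn for every seed so the TR stream is ABA-invariant
      lagZ <- rlnorm(design@seedsPerDish, meanlog = 0, sdlog = params@erLagShape)
      rate <- pmax(0, pmin((temp - params@tBase) / seeds$thetaCold,
                           (seeds$tc - temp) / params@thetaWarm))
      trTime <- ifelse(seeds$viable & rate > 0, 1 / rate, Inf)
      erTime <- trTime + lagMedian * lagZ
      trCount <- vapply(design@scoringTimes, function(t) sum(trTime <= t), 0L)
      erCount <- vapply(design@scoringTimes, function(t) sum(erTime <= t), 0L)
      k <- k + 1L
      res[[k]] <- data.frame(
        dish = sprintf("T%g_d%d", temp, dish), temperature_C = temp,
        time_d = design@scoringTimes, tr_count = trCount, er_count = erCount,
        dish_size = design@seedsPerDish, treatment_id = treatmentId)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Validate a table of germination records
#'
#' Checks the column contract of the long germination format and its
#' invariants: counts within `[0, dish_size]`, `er_count <= tr_count`, and
#' cumulative counts non-decreasing in time within each dish.
#'
#' @param records a data.frame of germination records.
#' @param integerCounts require integer counts (set to `FALSE` for
#'   expected-value curves used as noiseless fitting input).
#' @return the records, invisibly; errors name the offending rows.
#' @export
validateGerminationRecords <- function(records, integerCounts = TRUE) {
  req <- c("dish", "temperature_C", "time_d", "tr_count", "er_count", "dish_size")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(records) == 0L) return(invisible(records))
  bad <- which(!is.finite(records$tr_count) | !is.finite(records$er_count) |
               records$tr_count < 0 | records$er_count < 0 |
               records$tr_count > records$dish_size |
               records$er_count > records$tr_count)
  if (length(bad))
    stop("count invariant violated (need 0 <= er <= tr <= dish_size) at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  if (integerCounts &&
      any(records$tr_count != round(records$tr_count) |
          records$er_count != round(records$er_count)))
    stop("counts must be integers")
  for (d in unique(records$dish)) {
    sub <- records[records$dish == d, ]
    sub <- sub[order(sub$time_d), ]
    if (is.unsorted(sub$tr_count) || is.unsorted(sub$er_count))
      stop("cumulative counts decrease over time in dish '", d, "'")
  }
  invisible(records)
}

#' Expected-value germination records from the closed-form model
#'
#' Builds a single noiseless "dish" per temperature whose cumulative
#' percentages follow [predictCumulative()] exactly (fractional counts on a
#' unit dish).  Used as the deterministic oracle input for the fitting
#' pipeline; both events carry the thermal-time curve (no ER lag).
#'
#' @param temperatures temperatures (degC).
#' @param times scoring times; may differ per temperature when a list.
#' @param params a [SeedPopulationParams-class] object.
#' @return a germination-record data.frame with fractional counts.
#' @export
expectedRecords <- function(temperatures, times, params) {
  if (!is.list(times)) times <- rep(list(times), length(temperatures))
  stopifnot(length(times) == length(temperatures))
  out <- lapply(seq_along(temperatures), function(i) {
    f <- predictCumulative(temperatures[i], times[[i]], params)
    data.frame(dish = sprintf("expected_T%g", temperatures[i]),
               temperature_C = temperatures[i], time_d = times[[i]],
               tr_count = f, er_count = f, dish_size = 1,
               treatment_id = "expected")
  })
  do.call(rbind, out)
}
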