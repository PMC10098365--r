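.fixtureFile <- function() {
  system.file("extdata", "parameter_sets.json", package = "germtherm",
              mustWork = TRUE)
}

.fixtures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- jsonlite::read_json(.fixtureFile(),
                                                      simplifyVector = TRUE)
    cache
  }
})

#' Packaged seed-population parameter fixtures
#'
#' Named parameter sets for the dimorphic-seed morph/seedlot populations
#' (after-ripened black #1, brown #1, black #2, brown #2), each carrying a
#' default 9-point temperature grid for recovery experiments.  The cardinal
#' temperatures follow the published morph/seedlot estimates; distribution
#' SDs, the supra-optimal thermal-time constant and the temperature grids
#' are model design choices (see the methods vignette).
#'
#' @param name fixture name, one of [listSeedParamSets()].
#' @return `seedParamSet()`: a [SeedPopulationParams-class] object.
#' @examples
#' seedParamSet("black_AR_1")
#' @export
seedParamSet <- function(name) {
  sets <- .fixtures()$seed_params
  if (!name %in% names(sets))
    stop("unknown parameter set '", name, "'; available: ",
         paste(names(sets), collapse = ", "))
  p <- sets[[name]]
  seedPopulationParams(tBase = p$tBase, thetaCold50 = p$thetaCold50,
                       sigmaTheta = p$sigmaTheta, tc50 = p$tc50,
                       sigmaTc = p$sigmaTc, thetaWarm = p$thetaWarm,
                       pViable = p$pViable, erLag50 = p$erLag50,
                       erLagShape = p$erLagShape, label = p$label)
}

#' @rdname seedParamSet
#' @return `listSeedParamSets()`: the available fixture names.
#' @export
listSeedParamSets <- function() names(.fixtures()$seed_params)

#' @rdname seedParamSet
#' @return `fixtureTemperatures()`: the fixture's default temperature grid
#'   (degC).
#' @export
fixtureTemperatures <- function(name) {
  sets <- .fixtures()$seed_params
  if (!name %in% names(sets)) stop("unknown parameter set '", name, "'")
  as.numeric(sets[[name]]$temperatures)
}

#' @rdname seedParamSet
#' @return `fixtureScoringTimes()`: the default daily scoring grid (d).
#' @export
fixtureScoringTimes <- function() seq_len(.fixtures()$scoring_days)

#' Packaged dormancy-state and treatment-rule fixtures
#'
#' `dormancyStateFixture()` returns the layered dormancy composition of a
#' freshly harvested population (fractions calibrated so the simulated
#' treatment G_max ladder matches the published one);
#' `treatmentRulesFixture()` the matching [treatmentRules()] constants.
#'
#' @param name state name (currently `"FH_black_1"`).
#' @return a [DormancyState-class] object, or a rules list.
#' @examples
#' dormancyStateFixture("FH_black_1")
#' @export
dormancyStateFixture <- function(name = "FH_black_1") {
  sets <- .fixtures()$dormancy_states
  if (!name %in% names(sets))
    stop("unknown dormancy state '", name, "'; available: ",
         paste(names(sets), collapse = ", "))
  s <- sets[[name]]
  dormancyState(fNd = s$fNd, fNpd = s$fNpd, fDpd = s$fDpd)
}

#' @rdname dormancyStateFixture
#' @export
treatmentRulesFixture <- function() {
  r <- .fixtures()$treatment_rules
  treatmentRules(scarifiedFraction = r$scarifiedFraction,
                 fluridoneGaIncrement = r$fluridoneGaIncrement,
                 abaLagSlope = r$abaLagSlope)
}
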