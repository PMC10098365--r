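#' Construct treatment flags
#'
#' @param light seeds imbibed in light (default TRUE; germination of both
#'   morphs requires light).
#' @param afterRipened seeds dry-stored at room temperature before sowing.
#' @param scarified seed coat removed at the micropylar end.
#' @param ga exogenous GA4+7.
#' @param fluridone ABA-biosynthesis inhibitor (no dormancy release on its own).
#' @param abaConc exogenous ABA concentration (uM).
#' @param ethylene ethephon treatment.
#' @param nitrate KNO3 treatment.
#' @param coldStratified provenance flag; thermal effects enter through the
#'   imbibition temperature.
#' @return a validated [TreatmentFlags-class] object.
#' @examples
#' treatmentFlags(ga = TRUE, ethylene = TRUE, nitrate = TRUE)
#' @export
treatmentFlags <- function(light = TRUE, afterRipened = FALSE, scarified = FALSE,
                           ga = FALSE, fluridone = FALSE, abaConc = 0,
                           ethylene = FALSE, nitrate = FALSE,
                           coldStratified = FALSE) {
  new("TreatmentFlags", light = light, afterRipened = afterRipened,
      scarified = scarified, ga = ga, fluridone = fluridone,
      abaConc = as.numeric(abaConc), ethylene = ethylene, nitrate = nitrate,
      coldStratified = coldStratified)
}

#' Construct a dormancy state
#'
#' @param fNd non-dormant fraction of the viable population.
#' @param fNpd fraction with non-deep physiological dormancy (released by
#'   after-ripening or GA).
#' @param fDpd fraction with deeper dormancy (release additionally requires
#'   ethylene plus nitrate).
#' @return a validated [DormancyState-class] object; fractions must sum to 1.
#' @examples
#' dormancyState(fNd = 0.112, fNpd = 0.513, fDpd = 0.375)
#' @export
dormancyState <- function(fNd, fNpd, fDpd) {
  new("DormancyState", fNd = as.numeric(fNd), fNpd = as.numeric(fNpd),
      fDpd = as.numeric(fDpd))
}

#' Tunable constants of the treatment-response rules
#'
#' @param scarifiedFraction viable fraction released by coat removal (coat
#'   release can exceed non-deep-PD release).
#' @param fluridoneGaIncrement extra released fraction when fluridone is
#'   combined with GA (fluridone alone is a no-op).
#' @param abaLagSlope increase of the ER-lag multiplier per uM ABA
#'   (`multiplier = 1 + abaLagSlope * abaConc`).
#' @return a named list of rule constants.
#' @export
treatmentRules <- function(scarifiedFraction = 0.78, fluridoneGaIncrement = 0.05,
                           abaLagSlope = 0.15) {
  if (scarifiedFraction < 0 || scarifiedFraction > 1)
    stop("config error: scarifiedFraction must be in [0, 1]")
  if (fluridoneGaIncrement < 0 || fluridoneGaIncrement > 1)
    stop("config error: fluridoneGaIncrement must be in [0, 1]")
  if (abaLagSlope < 0) stop("config error: abaLagSlope must be >= 0")
  list(scarifiedFraction = scarifiedFraction,
       fluridoneGaIncrement = fluridoneGaIncrement,
       abaLagSlope = abaLagSlope)
}

#' Map a dormancy state and treatment to effective population parameters
#'
#' Encodes the treatment-response rules of the working model of testa- and
#' endosperm-rupture control: darkness blocks germination entirely; with no
#' releasing treatment only the non-dormant fraction germinates;
#' after-ripening or GA additionally release the non-deep-PD layer (fluridone
#' adds a small increment, but only in combination with GA); GA plus ethylene
#' plus nitrate release the full population; scarification releases a
#' configurable coat-release fraction.  Exogenous ABA scales the
#' TR-to-ER lag only and never affects TR timing.  Cold acts through the
#' thermal-time model itself (both events are delayed at low temperature), so
#' `coldStratified` changes no parameter.
#'
#' @param state a [DormancyState-class] object.
#' @param flags a [TreatmentFlags-class] object.
#' @param base the [SeedPopulationParams-class] set of the fully released
#'   population (its `pViable` is the viability ceiling).
#' @param rules constants from [treatmentRules()].
#' @return a [SeedPopulationParams-class] object with treatment-adjusted
#'   `pViable` and `lagMultiplierAba`.
#' @examples
#' st <- dormancyState(0.112, 0.513, 0.375)
#' base <- seedPopulationParams(8, 144, 30, 35, 2, 99, pViable = 1)
#' pViable(applyTreatment(st, treatmentFlags(ga = TRUE), base))         # 0.625
#' pViable(applyTreatment(st, treatmentFlags(light = FALSE), base))     # 0
#' @export
applyTreatment <- function(state, flags, base, rules = treatmentRules()) {
  stopifnot(is(state, "DormancyState"), is(flags, "TreatmentFlags"),
            is(base, "SeedPopulationParams"))
  validObject(state); validObject(flags); validObject(base)

  released <- if (!flags@light) {
    0
  } else if (flags@ga && flags@ethylene && flags@nitrate) {
    state@fNd + state@fNpd + state@fDpd
  } else if (flags@ga || flags@afterRipened) {
    r <- state@fNd + state@fNpd
    if (flags@ga && flags@fluridone) r <- r + rules$fluridoneGaIncrement
    min(r, 1)
  } else {
    state@fNd
  }
  if (flags@light && flags@scarified)
    released <- max(released, rules$scarifiedFraction)

  lagMult <- 1 + rules$abaLagSlope * flags@abaConc
  out <- base
  out@pViable <- released * base@pViable
  out@lagMultiplierAba <- lagMult
  validObject(out)
  out
}
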