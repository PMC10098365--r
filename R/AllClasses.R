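#' @import methods
#' @importFrom stats lm coef residuals pnorm qnorm rlnorm runif rbinom median sd approx setNames
#' @importFrom utils read.csv write.csv head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
NULL

#' Seed-population thermal-time parameters
#'
#' Parameters of the population-based thermal-time threshold model for one
#' seed morph / seedlot / dormancy state.  Germination rate of an individual
#' seed is piecewise linear in temperature: \eqn{(T - T_{base})/\Theta_{cold}}
#' below the seed's own optimum and \eqn{(T_c - T)/\theta_{warm}} above it.
#' The sub-optimal thermal-time constant \eqn{\Theta_{cold}} and the ceiling
#' temperature \eqn{T_c} are normally distributed across the population;
#' \eqn{T_{base}} and \eqn{\theta_{warm}} are common to all seeds.
#'
#' @slot tBase base temperature (degC) below which no germination occurs.
#' @slot thetaCold50 median sub-optimal thermal-time constant (degC d).
#' @slot sigmaTheta population SD of the thermal-time constant (degC d).
#' @slot tc50 median ceiling temperature (degC).
#' @slot sigmaTc population SD of the ceiling temperature (degC).
#' @slot thetaWarm supra-optimal thermal-time constant (degC d), shared.
#' @slot pViable fraction of seeds capable of germinating in this state.
#' @slot erLag50 median lag (d) between testa rupture and endosperm rupture.
#' @slot erLagShape lognormal shape (sdlog) of the TR-to-ER lag.
#' @slot lagMultiplierAba multiplicative ER-lag factor (>= 1), e.g. under ABA.
#' @slot label free-text identifier of the parameter set.
#'
#' @seealso [seedPopulationParams()], [germinationRate()], [predictCumulative()]
#' @export
setClass("SeedPopulationParams",
  representation(
    tBase = "numeric", thetaCold50 = "numeric", sigmaTheta = "numeric",
    tc50 = "numeric", sigmaTc = "numeric", thetaWarm = "numeric",
    pViable = "numeric", erLag50 = "numeric", erLagShape = "numeric",
    lagMultiplierAba = "numeric", label = "character"
  ),
  prototype(
    erLag50 = 0.75, erLagShape = 0.25, lagMultiplierAba = 1, label = ""
  )
)

setValidity("SeedPopulationParams", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  for (s in c("tBase", "thetaCold50", "sigmaTheta", "tc50", "sigmaTc",
              "thetaWarm", "pViable", "erLag50", "erLagShape",
              "lagMultiplierAba")) {
    if (!num1(slot(object, s))) msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
  }
  if (length(msg)) return(msg)
  if (object@tBase >= object@tc50) msg <- c(msg, "tBase must be < tc50")
  if (object@thetaCold50 <= 0) msg <- c(msg, "thetaCold50 must be > 0")
  if (object@thetaWarm <= 0) msg <- c(msg, "thetaWarm must be > 0")
  if (object@sigmaTheta < 0) msg <- c(msg, "sigmaTheta must be >= 0")
  if (object@sigmaTc < 0) msg <- c(msg, "sigmaTc must be >= 0")
  if (object@pViable < 0 || object@pViable > 1) msg <- c(msg, "pViable must be in [0, 1]")
  if (object@erLag50 < 0) msg <- c(msg, "erLag50 must be >= 0")
  if (object@lagMultiplierAba < 1) msg <- c(msg, "lagMultiplierAba must be >= 1")
  if (!length(msg)) {
    # implied optimum must lie strictly inside (tBase, tc50)
    topt <- (object@thetaWarm * object@tBase + object@thetaCold50 * object@tc50) /
      (object@thetaWarm + object@thetaCold50)
    if (!(topt > object@tBase && topt < object@tc50))
      msg <- c(msg, "implied T_opt does not lie between tBase and tc50")
  }
  if (length(msg)) msg else TRUE
})

#' Treatment flags applied to imbibed seeds
#'
#' Boolean treatment switches plus an ABA dose, mirroring the classical
#' germination-assay treatments (light, after-ripening, scarification,
#' gibberellin, fluridone, ethylene/ethephon, nitrate, cold stratification).
#'
#' @slot light logical; germination requires light.
#' @slot afterRipened logical; dry-stored (after-ripened) seeds.
#' @slot scarified logical; seed coat removed at the micropylar end.
#' @slot ga logical; exogenous gibberellin (GA4+7).
#' @slot fluridone logical; ABA-biosynthesis inhibitor.
#' @slot abaConc exogenous ABA concentration (uM, >= 0).
#' @slot ethylene logical; ethephon treatment.
#' @slot nitrate logical; KNO3 treatment.
#' @slot coldStratified logical; recorded for provenance, thermal effects are
#'   carried by the imbibition temperature itself.
#' @seealso [treatmentFlags()], [applyTreatment()]
#' @export
setClass("TreatmentFlags",
  representation(
    light = "logical", afterRipened = "logical", scarified = "logical",
    ga = "logical", fluridone = "logical", abaConc = "numeric",
    ethylene = "logical", nitrate = "logical", coldStratified = "logical"
  ),
  prototype(light = TRUE, afterRipened = FALSE, scarified = FALSE,
            ga = FALSE, fluridone = FALSE, abaConc = 0,
            ethylene = FALSE, nitrate = FALSE, coldStratified = FALSE)
)

setValidity("TreatmentFlags", function(object) {
  msg <- character()
  for (s in c("light", "afterRipened", "scarified", "ga", "fluridone",
              "ethylene", "nitrate", "coldStratified")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v)) msg <- c(msg, sprintf("'%s' must be TRUE or FALSE", s))
  }
  if (length(object@abaConc) != 1L || !is.finite(object@abaConc) ||
      object@abaConc < 0) msg <- c(msg, "abaConc must be a scalar >= 0")
  if (length(msg)) msg else TRUE
})

#' Dormancy layering of a seed population
#'
#' Fractions of the viable population that are non-dormant (`fNd`), carry
#' non-deep physiological dormancy releasable by after-ripening or GA
#' (`fNpd`), or carry a deeper dormancy additionally requiring ethylene plus
#' nitrate (`fDpd`).  The three fractions sum to one.
#'
#' @slot fNd,fNpd,fDpd fractions in `[0, 1]`, summing to 1.
#' @seealso [dormancyState()], [applyTreatment()], [decomposeLayers()]
#' @export
setClass("DormancyState",
  representation(fNd = "numeric", fNpd = "numeric", fDpd = "numeric"))

setValidity("DormancyState", function(object) {
  f <- c(object@fNd, object@fNpd, object@fDpd)
  if (length(f) != 3L || any(!is.finite(f))) return("fractions must be finite scalars")
  if (any(f < 0) || any(f > 1)) return("fractions must be in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9) return("fNd + fNpd + fDpd must sum to 1 (tol 1e-9)")
  TRUE
})

#' Design of a replicate petri-dish germination experiment
#'
#' @slot temperatures imbibition temperatures (degC), one experiment per value.
#' @slot nDishes replicate dishes per temperature.
#' @slot seedsPerDish seeds sown per dish.
#' @slot scoringTimes strictly increasing scoring times (d).
#' @slot treatment a [TreatmentFlags-class] object.
#' @slot rngSeed integer seed; identical seeds give bit-identical datasets.
#' @seealso [experimentDesign()], [simulateExperiment()]
#' @export
setClass("ExperimentDesign",
  representation(
    temperatures = "numeric", nDishes = "integer", seedsPerDish = "integer",
    scoringTimes = "numeric", treatment = "TreatmentFlags", rngSeed = "integer"
  )
)

setValidity("ExperimentDesign", function(object) {
  msg <- character()
  if (length(object@temperatures) < 1L) msg <- c(msg, "at least one temperature is required")
  if (any(!is.finite(object@temperatures))) msg <- c(msg, "temperatures must be finite")
  if (length(object@nDishes) != 1L || object@nDishes < 1L) msg <- c(msg, "nDishes must be a positive count")
  if (length(object@seedsPerDish) != 1L || object@seedsPerDish < 1L) msg <- c(msg, "seedsPerDish must be a positive count")
  if (length(object@scoringTimes) < 1L || any(!is.finite(object@scoringTimes)) ||
      any(object@scoringTimes < 0) || is.unsorted(object@scoringTimes, strictly = TRUE))
    msg <- c(msg, "scoringTimes must be non-negative and strictly increasing")
  if (length(object@rngSeed) != 1L || is.na(object@rngSeed)) msg <- c(msg, "rngSeed must be a scalar integer")
  if (length(msg)) msg else TRUE
})

#' Result of the thermal-time fitting pipeline
#'
#' Cardinal temperatures and threshold-distribution parameters recovered from
#' germination time-courses by percentile-wise two-regime regression, together
#' with per-percentile regression diagnostics.
#'
#' @slot tBase,tOpt,tc50 estimated cardinal temperatures (degC); `tc50` is the
#'   median of the ceiling-temperature distribution.
#' @slot thetaCold50,sigmaTheta median and SD of the sub-optimal thermal-time
#'   constant distribution (degC d).
#' @slot sigmaTc SD of the ceiling-temperature distribution (degC).
#' @slot thetaWarm supra-optimal thermal-time constant (degC d).
#' @slot gmaxEstimate observed maximum germination percentage (% of sown seeds).
#' @slot gRef percentage used as the viable-fraction reference for the probit
#'   transform of percentiles.
#' @slot percentiles percentiles (% of sown seeds) entering the fit.
#' @slot event which scored event was fitted, `"er"` or `"tr"`.
#' @slot subDiagnostics,supraDiagnostics per-percentile regression tables
#'   (slope, intercept, r-squared, derived threshold, temperatures used).
#' @slot sigmaThetaDispersion,sigmaTcDispersion SD of the per-percentile
#'   estimates themselves (secondary dispersion diagnostic).
#' @seealso [fitThermalTime()]
#' @export
setClass("ThermalTimeFit",
  representation(
    tBase = "numeric", thetaCold50 = "numeric", sigmaTheta = "numeric",
    tc50 = "numeric", sigmaTc = "numeric", thetaWarm = "numeric",
    tOpt = "numeric", gmaxEstimate = "numeric", gRef = "numeric",
    percentiles = "numeric", event = "character",
    subDiagnostics = "data.frame", supraDiagnostics = "data.frame",
    sigmaThetaDispersion = "numeric", sigmaTcDispersion = "numeric"
  )
)

setValidity("ThermalTimeFit", function(object) {
  msg <- character()
  if (is.finite(object@thetaCold50) && object@thetaCold50 <= 0)
    msg <- c(msg, "thetaCold50 must be > 0")
  if (is.finite(object@thetaWarm) && object@thetaWarm <= 0)
    msg <- c(msg, "thetaWarm must be > 0")
  if (is.finite(object@tOpt) && is.finite(object@tBase) && is.finite(object@tc50) &&
      !(object@tBase < object@tOpt && object@tOpt < object@tc50))
    msg <- c(msg, "tOpt must lie strictly between tBase and tc50")
  if (length(msg)) msg else TRUE
})

#' Dormancy-layer decomposition
#'
#' @slot fNd,fNpd,fDpd fractions of the viable population (sum to 1).
#' @slot viableFraction full-release G_max / 100, the viability ceiling.
#' @slot ofTotal the same three fractions expressed per sown seed
#'   (i.e. multiplied by `viableFraction`).
#' @slot warnings character vector of clipping/consistency notes.
#' @seealso [decomposeLayers()]
#' @export
setClass("DormancyDecomposition",
  representation(fNd = "numeric", fNpd = "numeric", fDpd = "numeric",
                 viableFraction = "numeric", ofTotal = "numeric",
                 warnings = "character"))

setValidity("DormancyDecomposition", function(object) {
  f <- c(object@fNd, object@fNpd, object@fDpd)
  if (any(!is.finite(f)) || any(f < -1e-12)) return("fractions must be non-negative")
  if (abs(sum(f) - 1) > 1e-9) return("fractions must sum to 1 (tol 1e-9)")
  if (object@viableFraction < 0 || object@viableFraction > 1)
    return("viableFraction must be in [0, 1]")
  TRUE
})

#' qPCR Cq experiment container
#'
#' A [SummarizedExperiment-class] with genes as rows and samples as columns,
#' one `"cq"` assay of quantification-cycle values and a per-gene
#' amplification efficiency (`rowData(x)$efficiency`, fraction in `[0, 1]`
#' where 1 means perfect doubling).
#'
#' @seealso [CqExperiment()], [relativeQuantity()], [geNormM()]
#' @export
setClass("CqExperiment", contains = "SummarizedExperiment")

setValidity("CqExperiment", function(object) {
  msg <- character()
  if (!"cq" %in% SummarizedExperiment::assayNames(object))
    return("a 'cq' assay is required")
  cq <- SummarizedExperiment::assay(object, "cq")
  if (any(cq[!is.na(cq)] <= 0)) msg <- c(msg, "Cq values must be > 0")
  if (any(rowSums(!is.na(cq)) == 0L)) msg <- c(msg, "no gene may be entirely missing")
  eff <- SummarizedExperiment::rowData(object)$efficiency
  if (is.null(eff)) {
    msg <- c(msg, "rowData(x)$efficiency is required")
  } else if (any(!is.finite(eff)) || any(eff < 0) || any(eff > 1)) {
    msg <- c(msg, "efficiencies must be fractions in [0, 1]")
  }
  if (is.null(rownames(object))) msg <- c(msg, "gene (row) names are required")
  if (length(msg)) msg else TRUE
})

#' Reference-gene stability report
#'
#' geNorm-style expression-stability summary: per-gene M values (mean pairwise
#' log-ratio SD; lower is more stable), the stability ranking, the selected
#' reference pair, and the pairwise-variation series V(n/n+1).
#'
#' @slot mValues named numeric vector of M values.
#' @slot ranking gene ids ordered from most to least stable.
#' @slot references the selected reference genes (size `k`, default 2).
#' @slot pairwiseVariation named numeric V(n/n+1) series (may be empty).
#' @seealso [genormReport()], [selectReferences()]
#' @export
setClass("StabilityReport",
  representation(mValues = "numeric", ranking = "character",
                 references = "character", pairwiseVariation = "numeric"))

setValidity("StabilityReport", function(object) {
  msg <- character()
  if (any(object@mValues < 0)) msg <- c(msg, "M values must be >= 0")
  if (!all(object@references %in% names(object@mValues)))
    msg <- c(msg, "references must be among the scored genes")
  if (!setequal(object@ranking, names(object@mValues)))
    msg <- c(msg, "ranking must be a permutation of the scored genes")
  if (length(msg)) msg else TRUE
})
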