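#' Accessors for thermal-time parameter and fit objects
#'
#' `tBase()`, `tOpt()`, `tc50()`, `thetaCold50()`, `sigmaTheta()`,
#' `sigmaTc()`, `thetaWarm()` and `pViable()` extract the corresponding
#' cardinal-temperature / threshold-distribution quantities from
#' [SeedPopulationParams-class] and [ThermalTimeFit-class] objects.
#'
#' @param x a `SeedPopulationParams` or `ThermalTimeFit` object.
#' @return a numeric scalar.
#' @name thermal-accessors
#' @aliases tBase tOpt tc50 thetaCold50 sigmaTheta sigmaTc thetaWarm pViable
#' @examples
#' p <- seedPopulationParams(tBase = 8, thetaCold50 = 144, sigmaTheta = 30,
#'                           tc50 = 35, sigmaTc = 2, thetaWarm = 99)
#' tBase(p); tOpt(p)
NULL

#' @rdname thermal-accessors
#' @export
setGeneric("tBase", function(x) standardGeneric("tBase"))
#' @rdname thermal-accessors
#' @export
setGeneric("tOpt", function(x) standardGeneric("tOpt"))
#' @rdname thermal-accessors
#' @export
setGeneric("tc50", function(x) standardGeneric("tc50"))
#' @rdname thermal-accessors
#' @export
setGeneric("thetaCold50", function(x) standardGeneric("thetaCold50"))
#' @rdname thermal-accessors
#' @export
setGeneric("sigmaTheta", function(x) standardGeneric("sigmaTheta"))
#' @rdname thermal-accessors
#' @export
setGeneric("sigmaTc", function(x) standardGeneric("sigmaTc"))
#' @rdname thermal-accessors
#' @export
setGeneric("thetaWarm", function(x) standardGeneric("thetaWarm"))
#' @rdname thermal-accessors
#' @export
setGeneric("pViable", function(x) standardGeneric("pViable"))

for (cl in c("SeedPopulationParams", "ThermalTimeFit")) {
  setMethod("tBase", cl, function(x) x@tBase)
  setMethod("tc50", cl, function(x) x@tc50)
  setMethod("thetaCold50", cl, function(x) x@thetaCold50)
  setMethod("sigmaTheta", cl, function(x) x@sigmaTheta)
  setMethod("sigmaTc", cl, function(x) x@sigmaTc)
  setMethod("thetaWarm", cl, function(x) x@thetaWarm)
}
setMethod("pViable", "SeedPopulationParams", function(x) x@pViable)
setMethod("tOpt", "ThermalTimeFit", function(x) x@tOpt)
setMethod("tOpt", "SeedPopulationParams", function(x)
  estimateTopt(x@tBase, x@thetaCold50, x@tc50, x@thetaWarm))

#' Dormancy-fraction accessors
#'
#' Extract the non-dormant (`fNd`), non-deep-PD (`fNpd`) and deeper-PD
#' (`fDpd`) fractions from [DormancyState-class] or
#' [DormancyDecomposition-class] objects.
#'
#' @param x a `DormancyState` or `DormancyDecomposition` object.
#' @return a numeric scalar.
#' @name dormancy-accessors
#' @aliases fNd fNpd fDpd
NULL

#' @rdname dormancy-accessors
#' @export
setGeneric("fNd", function(x) standardGeneric("fNd"))
#' @rdname dormancy-accessors
#' @export
setGeneric("fNpd", function(x) standardGeneric("fNpd"))
#' @rdname dormancy-accessors
#' @export
setGeneric("fDpd", function(x) standardGeneric("fDpd"))

for (cl in c("DormancyState", "DormancyDecomposition")) {
  setMethod("fNd", cl, function(x) x@fNd)
  setMethod("fNpd", cl, function(x) x@fNpd)
  setMethod("fDpd", cl, function(x) x@fDpd)
}

setMethod("show", "SeedPopulationParams", function(object) {
  cat("SeedPopulationParams",
      if (nzchar(object@label)) sprintf("'%s'", object@label) else "", "\n")
  cat(sprintf("  T_base %.2f degC | Theta_cold(50%%) %.1f +/- %.1f degC.d\n",
              object@tBase, object@thetaCold50, object@sigmaTheta))
  cat(sprintf("  T_c(50%%) %.2f +/- %.2f degC | theta_warm %.1f degC.d\n",
              object@tc50, object@sigmaTc, object@thetaWarm))
  cat(sprintf("  implied T_opt %.2f degC | p_viable %.2f | ER lag %.2f d (x%.2f)\n",
              tOpt(object), object@pViable, object@erLag50, object@lagMultiplierAba))
})

setMethod("show", "ThermalTimeFit", function(object) {
  cat("ThermalTimeFit (event:", object@event, ")\n")
  cat(sprintf("  T_base %.2f | T_opt %.2f | T_c(50%%) %.2f degC\n",
              object@tBase, object@tOpt, object@tc50))
  cat(sprintf("  Theta_cold(50%%) %.1f +/- %.1f degC.d | sigma_Tc %.2f degC | theta_warm %.1f degC.d\n",
              object@thetaCold50, object@sigmaTheta, object@sigmaTc, object@thetaWarm))
  cat(sprintf("  G_max %.1f%% | percentiles %s (G_ref %.1f%%)\n",
              object@gmaxEstimate, paste(object@percentiles, collapse = ","),
              object@gRef))
  cat(sprintf("  %d sub-optimal and %d supra-optimal percentile regressions\n",
              nrow(object@subDiagnostics), nrow(object@supraDiagnostics)))
})

setMethod("show", "DormancyState", function(object) {
  cat(sprintf("DormancyState: ND %.2f | nPD %.2f | dPD %.2f\n",
              object@fNd, object@fNpd, object@fDpd))
})

setMethod("show", "DormancyDecomposition", function(object) {
  cat("DormancyDecomposition (fractions of the viable population)\n")
  cat(sprintf("  ND %.3f | nPD %.3f | dPD %.3f | viable fraction %.3f\n",
              object@fNd, object@fNpd, object@fDpd, object@viableFraction))
  if (length(object@warnings))
    cat("  notes:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "TreatmentFlags", function(object) {
  on <- c(light = object@light, AR = object@afterRipened,
          scarified = object@scarified, GA = object@ga,
          fluridone = object@fluridone, ethylene = object@ethylene,
          nitrate = object@nitrate, cold = object@coldStratified)
  cat("TreatmentFlags:", if (any(on)) paste(names(on)[on], collapse = "+") else "none")
  if (object@abaConc > 0) cat(sprintf(" + ABA %g uM", object@abaConc))
  cat("\n")
})

setMethod("show", "ExperimentDesign", function(object) {
  cat(sprintf("ExperimentDesign: %d temperature(s), %d dishes x %d seeds, %d scoring times, seed %d\n",
              length(object@temperatures), object@nDishes, object@seedsPerDish,
              length(object@scoringTimes), object@rngSeed))
})

setMethod("show", "StabilityReport", function(object) {
  cat("StabilityReport (geNorm M; lower = more stable)\n")
  m <- sort(object@mValues)
  cat(" ", paste(sprintf("%s=%.3f", names(m), m), collapse = "  "), "\n")
  cat("  references:", paste(object@references, collapse = ", "), "\n")
})
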