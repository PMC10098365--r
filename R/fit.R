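# Pool replicate dishes at one temperature into a cumulative-% curve,
# monotonized by running maximum (scoring noise can transiently invert
# pooled percentages when dishes differ in size).
.pooledCurve <- function(records) {
  agg <- stats::aggregate(cbind(tr_count, er_count, dish_size) ~ time_d,
                          data = records, FUN = sum)
  agg <- agg[order(agg$time_d), ]
  data.frame(time_d = agg$time_d,
             tr_pct = cummax(100 * agg$tr_count / agg$dish_size),
             er_pct = cummax(100 * agg$er_count / agg$dish_size))
}

#' Interpolated times to reach given germination percentiles
#'
#' For the pooled cumulative percentage curve of one temperature, the time at
#' which each percentile `g` (% of sown seeds) is reached is found by linear
#' interpolation between the bracketing scoring times; a curve passing
#' exactly through `(t, g)` returns `t`.  Percentiles above the final
#' cumulative percentage are marked not reached.
#'
#' @param records germination records for a single temperature.
#' @param percentiles percentiles of sown seeds, in percent.
#' @param event `"er"` (default; germination is scored as endosperm rupture)
#'   or `"tr"`.
#' @return a data.frame with columns `temperature`, `percentile`, `time`,
#'   `reached`.
#' @examples
#' rec <- data.frame(dish = "d1", temperature_C = 24, time_d = 2:3,
#'                   tr_count = c(12, 18), er_count = c(12, 18),
#'                   dish_size = 30)
#' interpolatePercentileTimes(rec, 50)  # crosses 50% at t = 2.5
#' @export
interpolatePercentileTimes <- function(records, percentiles,
                                       event = c("er", "tr")) {
  event <- match.arg(event)
  if (nrow(records) == 0L) stop("input error: empty time-course")
  if (length(unique(records$temperature_C)) != 1L)
    stop("records must contain a single temperature; see germinationRateTable()")
  curve <- .pooledCurve(records)
  pct <- if (event == "er") curve$er_pct else curve$tr_pct
  tt <- c(0, curve$time_d)
  pp <- c(0, pct)
  final <- pct[length(pct)]
  res <- lapply(percentiles, function(g) {
    if (g > final) return(data.frame(temperature = records$temperature_C[1],
                                     percentile = g, time = NA_real_,
                                     reached = FALSE))
    i <- which(pp >= g)[1]
    t <- if (pp[i] == g || i == 1L) {
      # exact node (or reached at the first point with no bracket below)
      tt[i]
    } else {
      tt[i - 1] + (g - pp[i - 1]) / (pp[i] - pp[i - 1]) * (tt[i] - tt[i - 1])
    }
    data.frame(temperature = records$temperature_C[1], percentile = g,
               time = t, reached = TRUE)
  })
  do.call(rbind, res)
}

#' Germination-rate table over temperatures and percentiles
#'
#' Applies [interpolatePercentileTimes()] per temperature and converts times
#' to germination rates `GR = 1/t_g`.
#'
#' @param records germination records spanning one or more temperatures.
#' @inheritParams interpolatePercentileTimes
#' @return a data.frame with columns `temperature`, `percentile`, `time`,
#'   `reached`, `gr` (`NA` where the percentile was not reached).
#' @export
germinationRateTable <- function(records, percentiles, event = c("er", "tr")) {
  event <- match.arg(event)
  validateGerminationRecords(records, integerCounts = FALSE)
  out <- do.call(rbind, lapply(split(records, records$temperature_C),
    interpolatePercentileTimes, percentiles = percentiles, event = event))
  out$gr <- ifelse(out$reached & out$time > 0, 1 / out$time, NA_real_)
  rownames(out) <- NULL
  out
}

#' Split temperatures into sub- and supra-optimal regimes
#'
#' The regime boundary is the temperature with the highest germination rate
#' at the reference percentile (50, or the lowest common percentile when 50
#' is absent).  Temperatures strictly below it are sub-optimal, strictly
#' above supra-optimal, and the argmax temperature itself is assigned to
#' both.  A monotone increasing rate profile leaves the supra-optimal set
#' empty with a warning.
#'
#' @param grTable output of [germinationRateTable()].
#' @param referencePercentile percentile used to locate the rate maximum;
#'   default 50 when present, else the lowest percentile.
#' @return a list with `sub`, `supra` (temperature vectors) and `peak`.
#' @export
splitRegimes <- function(grTable, referencePercentile = NULL) {
  temps <- sort(unique(grTable$temperature))
  if (length(temps) < 3L) stop("fit error: fewer than 3 distinct temperatures")
  if (is.null(referencePercentile)) {
    pcts <- sort(unique(grTable$percentile))
    referencePercentile <- if (50 %in% pcts) 50 else min(pcts)
  }
  ref <- grTable[grTable$percentile == referencePercentile & !is.na(grTable$gr), ]
  if (nrow(ref) == 0L) stop("fit error: reference percentile never reached")
  peak <- ref$temperature[which.max(ref$gr)]
  sub <- temps[temps <= peak]
  supra <- temps[temps >= peak]
  if (length(supra) <= 1L)
    warning("rate profile is monotone increasing; supra-optimal set is empty, fitting sub-optimal regime only")
  list(sub = sub, supra = supra, peak = peak)
}

# Per-percentile OLS of GR on T.  Returns slope/intercept/r2 per percentile.
.percentileOLS <- function(grTable, minTemps) {
  out <- lapply(split(grTable, grTable$percentile), function(d) {
    d <- d[!is.na(d$gr), ]
    if (nrow(d) < minTemps) return(NULL)
    fit <- lm(gr ~ temperature, data = d)
    cf <- coef(fit)
    sst <- sum((d$gr - mean(d$gr))^2)
    r2 <- if (sst > 0) 1 - sum(residuals(fit)^2) / sst else 1
    data.frame(percentile = d$percentile[1], slope = cf[[2]],
               intercept = cf[[1]], r2 = r2,
               xIntercept = -cf[[1]] / cf[[2]], nTemps = nrow(d),
               temperatures = paste(sort(d$temperature), collapse = ","))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (!is.null(out)) rownames(out) <- NULL
  out
}

#' Sub-optimal regime regressions
#'
#' Ordinary least squares of germination rate on temperature, per
#' percentile, within the sub-optimal regime.  The slope of the percentile-g
#' line is `1/Theta_cold(g)` and its x-intercept estimates the (shared) base
#' temperature; the base temperature is reported from the 50th-percentile
#' regression (or the closest available percentile), with all per-percentile
#' intercepts retained as diagnostics.
#'
#' @param grTable rate table restricted to sub-optimal temperatures.
#' @param minTemps minimum temperatures per percentile (hard error below 3).
#' @return a data.frame with per-percentile `slope`, `intercept`, `r2`,
#'   `xIntercept`, `theta` (= 1/slope) and an attribute `tBase`.
#' @examples
#' g <- expand.grid(temperature = c(12, 16, 20, 24), percentile = 50)
#' g$gr <- (g$temperature - 8) / 144
#' fitSuboptimal(g)  # recovers tBase = 8, theta = 144
#' @export
fitSuboptimal <- function(grTable, minTemps = 3) {
  if (minTemps < 3) stop("fit error: at least 3 temperatures per percentile are required")
  if (!"gr" %in% names(grTable)) stop("'grTable' must carry a 'gr' column")
  ok <- .percentileOLS(grTable, minTemps)
  if (is.null(ok)) stop("fit error: no percentile has >= ", minTemps,
                        " sub-optimal temperatures")
  if (any(ok$slope <= 1e-12))
    stop("regime misassignment: non-positive sub-optimal slope at percentile(s) ",
         paste(ok$percentile[ok$slope <= 0], collapse = ", "))
  ok$theta <- 1 / ok$slope
  refP <- if (any(ok$percentile <= 50)) max(ok$percentile[ok$percentile <= 50]) else min(ok$percentile)
  attr(ok, "tBase") <- ok$xIntercept[ok$percentile == refP]
  attr(ok, "referencePercentile") <- refP
  ok
}

#' Supra-optimal regime regressions
#'
#' Per-percentile OLS of germination rate on temperature above the optimum.
#' The x-intercept of the percentile-g line is the ceiling temperature
#' `T_c(g)`; the common supra-optimal thermal-time constant is the negative
#' reciprocal of the median slope.
#'
#' @inheritParams fitSuboptimal
#' @return a data.frame with per-percentile `slope`, `intercept`, `r2`,
#'   `tc` (x-intercept) and an attribute `thetaWarm`.
#' @examples
#' g <- expand.grid(temperature = c(26, 28, 30, 32), percentile = 50)
#' g$gr <- (35 - g$temperature) / 99
#' fitSupraoptimal(g)  # recovers tc = 35, thetaWarm = 99
#' @export
fitSupraoptimal <- function(grTable, minTemps = 3) {
  if (minTemps < 3) stop("fit error: at least 3 temperatures per percentile are required")
  if (!"gr" %in% names(grTable)) stop("'grTable' must carry a 'gr' column")
  ok <- .percentileOLS(grTable, minTemps)
  if (is.null(ok)) stop("fit error: no percentile has >= ", minTemps,
                        " supra-optimal temperatures")
  if (any(ok$slope >= -1e-12))
    stop("regime misassignment: non-negative supra-optimal slope at percentile(s) ",
         paste(ok$percentile[ok$slope >= 0], collapse = ", "))
  ok$tc <- ok$xIntercept
  attr(ok, "thetaWarm") <- -1 / median(ok$slope)
  ok
}

#' Probit fit of a threshold distribution
#'
#' Regresses per-percentile threshold values on the standard-normal quantile
#' of the percentile rank within the viable population,
#' `Phi^-1(g / gRef)`; the intercept estimates the population median and the
#' (sign-corrected) slope the SD.
#'
#' @param values per-percentile threshold estimates (e.g. `Theta_cold(g)` or
#'   `T_c(g)`).
#' @param percentiles matching percentiles, % of sown seeds.
#' @param gRef viable-fraction reference percentage (ranks are
#'   `percentiles / gRef`).
#' @return list with `median`, `sd`, `slope` (signed) and `dispersion`
#'   (plain SD of the per-percentile values, a secondary diagnostic).
#' @examples
#' g <- c(20, 35, 50)
#' fitThresholdDistribution(144 + 30 * qnorm(g / 100), g, gRef = 100)
#' @export
fitThresholdDistribution <- function(values, percentiles, gRef = 100) {
  keep <- is.finite(values) & is.finite(percentiles)
  values <- values[keep]; percentiles <- percentiles[keep]
  if (length(unique(percentiles)) < 2L)
    stop("fit error: at least 2 distinct percentiles are required")
  if (any(percentiles <= 0) || any(percentiles >= gRef))
    stop("percentiles must lie strictly inside (0, gRef)")
  z <- qnorm(percentiles / gRef)
  fit <- lm(values ~ z)
  cf <- coef(fit)
  list(median = cf[[1]], sd = abs(cf[[2]]), slope = cf[[2]],
       dispersion = if (length(values) > 1) sd(values) else 0)
}

# Decide where the shared peak temperature belongs for one percentile:
# extrapolate the strictly-sub-optimal line to the peak; a rate clearly
# below it means the percentile is already ceiling-limited there.
.peakRegime <- function(d, peak, tol) {
  below <- d[d$temperature < peak & !is.na(d$gr), ]
  atPeak <- d$gr[d$temperature == peak]
  if (!length(atPeak) || is.na(atPeak[1])) return("none")
  if (nrow(below) < 2L) return("both")
  cf <- coef(lm(gr ~ temperature, data = below))
  pred <- cf[[1]] + cf[[2]] * peak
  if (is.finite(pred) && atPeak[1] < (1 - tol) * pred) "supra" else "sub"
}

#' Fit the population thermal-time threshold model to germination records
#'
#' End-to-end inverse pipeline: pools replicate dishes, interpolates
#' percentile germination times, converts them to rates, splits temperatures
#' into sub- and supra-optimal regimes, runs per-percentile OLS in each
#' regime, fits the threshold distributions by probit regression and derives
#' the optimal temperature from the two median lines.
#'
#' Percentiles are percent of *sown* seeds (10, 20, ... up to the largest
#' multiple of `percentileStep` strictly below the observed maximum
#' germination percentage); the probit transform uses the observed maximum
#' as the viable-fraction reference, so ranks are quantiles within the
#' viable population.
#'
#' The shared argmax temperature is handled by `peakRule`:
#' `"consistency"` (default) assigns it per percentile to the sub-optimal
#' line only when the observed rate there is within `peakTol` (relative) of
#' the extrapolated strictly-sub-optimal line, and to the supra-optimal line
#' otherwise — near the optimum the ceiling distribution already bends the
#' rate profile below the cold line for part of the population; `"both"`
#' includes the peak point in both regressions.
#'
#' @param records germination records (several temperatures).
#' @param percentiles percentiles to use; `NULL` (default) derives them from
#'   the observed maximum germination.
#' @param event fitted event, `"er"` (default) or `"tr"`.
#' @param minTemps minimum temperatures per percentile and regime (hard
#'   error below 3); percentiles with fewer usable temperatures in a regime
#'   are dropped from that regime.
#' @param peakRule `"consistency"` or `"both"`, see Details.
#' @param peakTol relative tolerance of the consistency rule.
#' @param percentileStep spacing of the automatic percentile grid.
#' @param lagCorrection when fitting endosperm-rupture times and testa
#'   rupture was scored too, subtract the median observed TR-to-ER lag from
#'   the ER percentile times before converting to rates, so the thermal-time
#'   clock refers to the start of the rupture cascade rather than absorbing
#'   the lag into the cardinal temperatures.  Ignored for `event = "tr"` or
#'   when the two events coincide.
#' @return a [ThermalTimeFit-class] object.  Supra-optimal slots are `NA`
#'   (with a warning) when too few percentiles reach the supra-optimal
#'   regime.
#' @examples
#' p <- seedPopulationParams(8, 144, 30, 35, 2, 99, pViable = 0.6)
#' d <- experimentDesign(c(13, 15, 17, 19, 22, 25, 28, 31, 34),
#'                       scoringTimes = 1:45, rngSeed = 42)
#' fit <- fitThermalTime(simulateExperiment(d, p))
#' tBase(fit)
#' @export
fitThermalTime <- function(records, percentiles = NULL, event = c("er", "tr"),
                           minTemps = 3, peakRule = c("consistency", "both"),
                           peakTol = 0.1, percentileStep = 10,
                           lagCorrection = TRUE) {
  event <- match.arg(event)
  peakRule <- match.arg(peakRule)
  validateGerminationRecords(records, integerCounts = FALSE)
  temps <- sort(unique(records$temperature_C))
  if (length(temps) < 4L)
    stop("fit error [input]: records must span at least 4 temperatures")

  # observed G_max (pooled, per temperature) and percentile grid
  col <- if (event == "er") "er_pct" else "tr_pct"
  finals <- vapply(split(records, records$temperature_C),
                   function(r) { cv <- .pooledCurve(r); cv[[col]][nrow(cv)] }, 0)
  gmaxObs <- max(finals)
  if (is.null(percentiles)) {
    percentiles <- seq(percentileStep, 100, by = percentileStep)
    percentiles <- percentiles[percentiles < gmaxObs]
  }
  if (length(percentiles) < 2L)
    stop(sprintf(
      "fit error [percentiles]: observed maximum germination (%.1f%%) supports fewer than 2 percentiles; cannot fit threshold distributions",
      gmaxObs))
  gRef <- gmaxObs

  gr <- germinationRateTable(records, percentiles, event)
  if (lagCorrection && event == "er" &&
      any(records$tr_count != records$er_count)) {
    trGr <- germinationRateTable(records, percentiles, "tr")
    both <- gr$reached & trGr$reached
    lagHat <- median(gr$time[both] - trGr$time[both], na.rm = TRUE)
    if (is.finite(lagHat) && lagHat > 0) {
      corrected <- gr$time - lagHat
      gr$gr <- ifelse(gr$reached & corrected > 0, 1 / corrected, NA_real_)
    }
  }
  regimes <- splitRegimes(gr)
  peak <- regimes$peak

  subRows <- list(); supraRows <- list()
  for (d in split(gr, gr$percentile)) {
    where <- if (peakRule == "both") "both" else .peakRegime(d, peak, peakTol)
    subSel <- d$temperature < peak
    supraSel <- d$temperature > peak
    if (where %in% c("sub", "both")) subSel <- subSel | d$temperature == peak
    if (where %in% c("supra", "both")) supraSel <- supraSel | d$temperature == peak
    subRows[[length(subRows) + 1L]] <- d[subSel & !is.na(d$gr), ]
    supraRows[[length(supraRows) + 1L]] <- d[supraSel & !is.na(d$gr), ]
  }
  subTab <- do.call(rbind, subRows)
  supraTab <- do.call(rbind, supraRows)

  # drop percentiles with too few temperatures, then run the strict fitters
  keepEnough <- function(tab) {
    n <- table(tab$percentile)
    tab[tab$percentile %in% as.numeric(names(n)[n >= minTemps]), ]
  }
  subTab <- keepEnough(subTab)
  if (nrow(subTab) == 0L)
    stop("fit error [suboptimal]: no percentile reached at >= ", minTemps,
         " sub-optimal temperatures")
  subFit <- tryCatch(fitSuboptimal(subTab, minTemps),
                     error = function(e) stop("fit error [suboptimal]: ",
                                              conditionMessage(e), call. = FALSE))
  thetaDist <- if (nrow(subFit) >= 2L) {
    fitThresholdDistribution(subFit$theta, subFit$percentile, gRef)
  } else {
    list(median = subFit$theta[1], sd = NA_real_, slope = NA_real_, dispersion = 0)
  }

  supraTab <- keepEnough(supraTab)
  supraFit <- NULL; tcDist <- NULL
  if (nrow(supraTab) > 0L && length(unique(supraTab$percentile)) >= 2L) {
    supraFit <- tryCatch(fitSupraoptimal(supraTab, minTemps),
                         error = function(e) NULL)
    if (!is.null(supraFit) && nrow(supraFit) >= 2L)
      tcDist <- fitThresholdDistribution(supraFit$tc, supraFit$percentile, gRef)
  }
  if (is.null(tcDist))
    warning("supra-optimal regime could not be fitted (too few temperatures above the optimum); ceiling-temperature slots are NA")

  tBaseHat <- attr(subFit, "tBase")
  thetaWarmHat <- if (!is.null(supraFit)) attr(supraFit, "thetaWarm") else NA_real_
  tc50Hat <- if (!is.null(tcDist)) tcDist$median else NA_real_
  sigmaTcHat <- if (!is.null(tcDist)) tcDist$sd else NA_real_
  toptHat <- if (is.finite(tc50Hat) && is.finite(thetaWarmHat) &&
                 is.finite(thetaDist$median))
    estimateTopt(tBaseHat, thetaDist$median, tc50Hat, thetaWarmHat) else NA_real_

  new("ThermalTimeFit",
      tBase = tBaseHat, thetaCold50 = thetaDist$median,
      sigmaTheta = thetaDist$sd, tc50 = tc50Hat, sigmaTc = sigmaTcHat,
      thetaWarm = thetaWarmHat, tOpt = toptHat, gmaxEstimate = gmaxObs,
      gRef = gRef, percentiles = percentiles, event = event,
      subDiagnostics = subFit,
      supraDiagnostics = if (is.null(supraFit)) data.frame() else supraFit,
      sigmaThetaDispersion = thetaDist$dispersion,
      sigmaTcDispersion = if (is.null(tcDist)) NA_real_ else tcDist$dispersion)
}

#' Convert a thermal-time fit to a flat list / JSON-ready report
#'
#' @param fit a [ThermalTimeFit-class] object.
#' @return a named list of all headline estimates plus the diagnostic tables.
#' @export
fitReport <- function(fit) {
  stopifnot(is(fit, "ThermalTimeFit"))
  list(tBase = fit@tBase, thetaCold50 = fit@thetaCold50,
       sigmaTheta = fit@sigmaTheta, tc50 = fit@tc50, sigmaTc = fit@sigmaTc,
       thetaWarm = fit@thetaWarm, tOpt = fit@tOpt,
       gmaxEstimate = fit@gmaxEstimate, gRef = fit@gRef,
       percentiles = fit@percentiles, event = fit@event,
       sigmaThetaDispersion = fit@sigmaThetaDispersion,
       sigmaTcDispersion = fit@sigmaTcDispersion,
       subDiagnostics = fit@subDiagnostics,
       supraDiagnostics = fit@supraDiagnostics)
}
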