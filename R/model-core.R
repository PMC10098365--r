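#' Construct a seed-population parameter set
#'
#' @param tBase base temperature (degC).
#' @param thetaCold50 median sub-optimal thermal-time constant (degC d).
#' @param sigmaTheta SD of the thermal-time constant across the population.
#' @param tc50 median ceiling temperature (degC).
#' @param sigmaTc SD of the ceiling temperature across the population.
#' @param thetaWarm supra-optimal thermal-time constant (degC d).
#' @param pViable fraction of seeds capable of germinating (default 1).
#' @param erLag50 median testa-rupture to endosperm-rupture lag (d).
#' @param erLagShape lognormal sdlog of the lag distribution.
#' @param lagMultiplierAba multiplicative ER-lag factor (>= 1).
#' @param label free-text identifier.
#' @return a validated [SeedPopulationParams-class] object.
#' @examples
#' seedPopulationParams(tBase = 8, thetaCold50 = 144, sigmaTheta = 30,
#'                      tc50 = 35, sigmaTc = 2, thetaWarm = 99, pViable = 0.6)
#' @export
seedPopulationParams <- function(tBase, thetaCold50, sigmaTheta, tc50, sigmaTc,
                                 thetaWarm, pViable = 1, erLag50 = 0.75,
                                 erLagShape = 0.25, lagMultiplierAba = 1,
                                 label = "") {
  new("SeedPopulationParams", tBase = as.numeric(tBase),
      thetaCold50 = as.numeric(thetaCold50), sigmaTheta = as.numeric(sigmaTheta),
      tc50 = as.numeric(tc50), sigmaTc = as.numeric(sigmaTc),
      thetaWarm = as.numeric(thetaWarm), pViable = as.numeric(pViable),
      erLag50 = as.numeric(erLag50), erLagShape = as.numeric(erLagShape),
      lagMultiplierAba = as.numeric(lagMultiplierAba), label = label)
}

#' Draw individual seeds from a population parameter set
#'
#' Each seed receives a uniform quantile rank `u`; its thermal-time constant
#' is the `u` quantile of the Theta_cold normal and its ceiling temperature
#' the `1 - u` quantile of the T_c normal (comonotonic thresholds: seeds that
#' germinate fast at sub-optimal temperatures also tolerate the warmest
#' temperatures).  Draws violating `thetaCold > 0` or `tc > tBase` are
#' redrawn (rejection), keeping every seed physically valid.  Viability is an
#' independent Bernoulli(`pViable`) draw.
#'
#' @param n number of seeds.
#' @param params a [SeedPopulationParams-class] object.
#' @return a data.frame with columns `quantileRank`, `thetaCold`, `tc`,
#'   `viable`.
#' @examples
#' set.seed(1)
#' p <- seedPopulationParams(8, 144, 30, 35, 2, 99, pViable = 0.6)
#' head(drawSeeds(5, p))
#' @export
drawSeeds <- function(n, params) {
  stopifnot(is(params, "SeedPopulationParams"))
  validObject(params)
  u <- runif(n)
  theta <- params@thetaCold50 + params@sigmaTheta * qnorm(u)
  tc <- params@tc50 - params@sigmaTc * qnorm(u)
  bad <- which(theta <= 0 | tc <= params@tBase)
  guard <- 0L
  while (length(bad)) {
    u[bad] <- runif(length(bad))
    theta[bad] <- params@thetaCold50 + params@sigmaTheta * qnorm(u[bad])
    tc[bad] <- params@tc50 - params@sigmaTc * qnorm(u[bad])
    bad <- bad[theta[bad] <= 0 | tc[bad] <= params@tBase]
    guard <- guard + 1L
    if (guard > 1000L) stop("rejection sampling failed; parameter set places most mass outside the valid region")
  }
  data.frame(quantileRank = u, thetaCold = theta, tc = tc,
             viable = runif(n) < params@pViable)
}

#' Per-seed germination rate as a function of temperature
#'
#' Piecewise-linear rate: `(T - tBase)/thetaCold` up to the seed's own
#' optimum (the intersection of its two lines) and `(tc - T)/thetaWarm`
#' above it, floored at zero.  Both branches equal their minimum, so the
#' rate is computed as `max(0, min(sub, supra))`.
#'
#' @param temperature imbibition temperature(s), degC.
#' @param seed one row of [drawSeeds()] output (or a list with `thetaCold`,
#'   `tc`, `viable`).
#' @param params a [SeedPopulationParams-class] object.
#' @return germination rate(s), 1/d.  Zero at and beyond the cardinal
#'   temperatures.
#' @examples
#' p <- seedPopulationParams(8, 144, 30, 35, 2, 99)
#' s <- list(thetaCold = 144, tc = 35, viable = TRUE)
#' germinationRate(24, s, p)   # (24 - 8)/144 = 0.1111
#' @export
germinationRate <- function(temperature, seed, params) {
  stopifnot(is(params, "SeedPopulationParams"))
  if (any(!is.finite(temperature))) stop("'temperature' must be finite")
  if (!isTRUE(all(seed$viable))) stop("germination rate is defined for viable seeds only")
  sub <- (temperature - params@tBase) / seed$thetaCold
  supra <- (seed$tc - temperature) / params@thetaWarm
  pmax(0, pmin(sub, supra))
}

#' Time to germination of an individual seed
#'
#' Reciprocal of [germinationRate()].  Temperatures at or below the base,
#' at or above the seed's ceiling, or a non-viable seed yield `Inf`, the
#' non-germinating marker.
#'
#' @inheritParams germinationRate
#' @return time(s) to germination in days, `Inf` when the seed never
#'   germinates at that temperature.
#' @examples
#' p <- seedPopulationParams(8, 144, 30, 35, 2, 99)
#' s <- list(thetaCold = 144, tc = 35, viable = TRUE)
#' timeToGermination(24, s, p)  # 144/16 = 9 d
#' @export
timeToGermination <- function(temperature, seed, params) {
  if (!isTRUE(all(seed$viable))) return(rep(Inf, length(temperature)))
  r <- germinationRate(temperature, seed, params)
  ifelse(r > 0, 1 / r, Inf)
}

#' Expected cumulative germinated fraction over time
#'
#' Closed form of the population model at one temperature.  At sub-optimal
#' temperatures the germinated fraction at time t is
#' `pViable * Phi(((T - tBase) t - thetaCold50) / sigmaTheta)`; at
#' supra-optimal temperatures the ceiling distribution limits it to
#' `pViable * Phi((tc50 - T - thetaWarm/t) / sigmaTc)`.  With comonotonic
#' thresholds the germinated fraction is the minimum of the two, which
#' covers both regimes in a single expression.  A zero SD collapses the
#' corresponding term to a step function.
#'
#' @param temperature one imbibition temperature (degC).
#' @param times non-negative, ascending scoring times (d).
#' @param params a [SeedPopulationParams-class] object.
#' @return expected germinated fraction of sown seeds at each time
#'   (non-decreasing, bounded by `pViable`).
#' @examples
#' p <- seedPopulationParams(8, 144, 30, 35, 2, 99)
#' predictCumulative(24, c(6, 9, 14), p)  # 0.5 at t = 9
#' @export
predictCumulative <- function(temperature, times, params) {
  stopifnot(is(params, "SeedPopulationParams"))
  validObject(params)
  if (length(temperature) != 1L || !is.finite(temperature))
    stop("'temperature' must be a finite scalar")
  if (any(!is.finite(times)) || any(times < 0)) stop("'times' must be non-negative")
  if (is.unsorted(times)) stop("'times' must be ascending")
  if (temperature <= params@tBase) return(rep(0, length(times)))
  step <- function(x) as.numeric(x >= 0)
  xsub <- (temperature - params@tBase) * times - params@thetaCold50
  psub <- if (params@sigmaTheta == 0) step(xsub) else pnorm(xsub / params@sigmaTheta)
  xsup <- params@tc50 - temperature - ifelse(times > 0, params@thetaWarm / times, Inf)
  psup <- if (params@sigmaTc == 0) step(xsup) else pnorm(xsup / params@sigmaTc)
  params@pViable * pmin(psub, psup)
}

#' Optimal temperature from the two median rate lines
#'
#' Intersection of the sub-optimal median rate line
#' `(T - tBase)/thetaCold50` with the supra-optimal line
#' `(tc50 - T)/thetaWarm`; the unique solution lies strictly between the
#' base and ceiling temperatures.
#'
#' @param tBase base temperature (degC).
#' @param thetaCold50 median sub-optimal thermal-time constant (degC d, > 0).
#' @param tc50 median ceiling temperature (degC, > `tBase`).
#' @param thetaWarm supra-optimal thermal-time constant (degC d, > 0).
#' @return the optimal temperature (degC).
#' @examples
#' estimateTopt(8, 144, 35, 99)      # 24
#' estimateTopt(10.5, 120, 33.5, 120)  # midpoint 22
#' @export
estimateTopt <- function(tBase, thetaCold50, tc50, thetaWarm) {
  if (any(!is.finite(c(tBase, thetaCold50, tc50, thetaWarm))))
    stop("all arguments must be finite")
  if (thetaCold50 <= 0 || thetaWarm <= 0) stop("thermal-time constants must be > 0")
  if (tc50 <= tBase) stop("degenerate model: tc50 must exceed tBase")
  (thetaWarm * tBase + thetaCold50 * tc50) / (thetaWarm + thetaCold50)
}
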