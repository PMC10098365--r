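# Reference parameter set used across tests (after-ripened black seeds).
blackParams <- function(pViable = 0.6, erLag50 = 0.75) {
  seedPopulationParams(tBase = 8, thetaCold50 = 144, sigmaTheta = 30,
                       tc50 = 35, sigmaTc = 2, thetaWarm = 99,
                       pViable = pViable, erLag50 = erLag50)
}

# Independent closed-form oracle for the time at which percentile g (% of
# sown seeds) is reached: invert each threshold quantile by hand rather
# than through the package's predictCumulative/fit path.
oracleCrossingTime <- function(g, temperature, params) {
  rank <- g / (100 * params@pViable)
  if (rank <= 0 || rank >= 1) return(Inf)
  theta <- params@thetaCold50 + params@sigmaTheta * qnorm(rank)
  tc <- params@tc50 - params@sigmaTc * qnorm(rank)
  tsub <- if (temperature > params@tBase) theta / (temperature - params@tBase) else Inf
  tsup <- if (tc > temperature) params@thetaWarm / (tc - temperature) else Inf
  max(tsub, tsup)  # time is the reciprocal of the binding (minimum) rate
}

# Noiseless expected-value dataset whose scoring grids contain the exact
# percentile crossing times, so interpolation hits exact nodes.
noiselessRecords <- function(params, temperatures, percentiles = seq(10, 50, 10),
                             horizon = 500) {
  times <- lapply(temperatures, function(T) {
    cross <- vapply(percentiles, oracleCrossingTime, 0,
                    temperature = T, params = params)
    sort(unique(c(1:45, cross[is.finite(cross) & cross <= horizon], horizon)))
  })
  expectedRecords(temperatures, times, params)
}

# Seed stride for replicate experiment loops, co-prime with the per-dish
# substream offsets used inside simulateExperiment().
seedStride <- 104729L
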