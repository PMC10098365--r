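---
title: "Population-based thermal-time modelling of dimorphic seed germination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-based thermal-time modelling of dimorphic seed germination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germtherm)
```

## The model

`germtherm` implements a population-based thermal-time threshold model for
seed germination, developed around the dimorphic (black/brown) seeds of
*Chenopodium album*. Germination of an individual seed proceeds through two
visible events, testa rupture (TR) and endosperm rupture (ER); ER completes
germination. The germination *rate* (reciprocal time to the event) of a
single seed is piecewise linear in the imbibition temperature $T$:

$$ GR(T) \;=\; \max\!\left(0,\; \min\!\left(\frac{T - T_{base}}{\Theta_{cold}},\;
   \frac{T_c - T}{\theta_{warm}}\right)\right) $$

Below the seed's own optimum the rate is governed by the sub-optimal
thermal-time constant $\Theta_{cold}$ (degree-days above the base
temperature $T_{base}$ required for germination); above it the rate falls
linearly to zero at the seed's ceiling temperature $T_c$. Across the
population $\Theta_{cold} \sim N(\Theta_{cold(50\%)}, \sigma_\Theta^2)$ and
$T_c \sim N(T_{c(50\%)}, \sigma_{T_c}^2)$, while $T_{base}$ and
$\theta_{warm}$ are shared — exactly the quantities for which the
morph/seedlot summaries report SDs. The two median lines intersect at the
optimal temperature $T_{opt}$ (`estimateTopt()`).

**Comonotonic thresholds.** Both per-seed thresholds are mapped from a
single uniform quantile: the seed at population rank $u$ receives the $u$
quantile of the $\Theta_{cold}$ distribution and the $1-u$ quantile of the
$T_c$ distribution, so the seeds that germinate fastest in the cold also
tolerate the warmest temperatures. The two-regression construction is
silent on this coupling; comonotonicity is the conventional
population-threshold assumption, keeps percentile ranks consistent across
regimes, and yields the closed form used by `predictCumulative()`:

$$ F(t \mid T) = p_{viable}\cdot\min\left\{
   \Phi\!\left(\frac{(T-T_{base})\,t - \Theta_{cold(50)}}{\sigma_\Theta}\right),\;
   \Phi\!\left(\frac{T_{c(50)} - T - \theta_{warm}/t}{\sigma_{T_c}}\right)\right\} $$

with zero SDs handled as step functions. Threshold draws are rejected and
redrawn when they violate $\Theta_{cold} > 0$ or $T_c > T_{base}$; the
closed form ignores this truncation, whose mass is $\Phi(-4.8)\approx 10^{-6}$
for the packaged fixtures — far below Monte-Carlo test tolerance.

## The simulator as the study design

`simulateExperiment()` realizes replicate petri-dish assays: 3 dishes of 30
seeds per temperature by default, scored daily (events recorded at the
first scoring time at or after the event — daily bins, closed on the
right). Viability is Bernoulli($p_{viable}$). The TR time is the
thermal-time prediction; ER adds a lognormal lag (median `erLag50` = 0.75 d,
sdlog 0.25 — lognormal keeps lags positive; the published time-courses show
TR leading ER by roughly a day but tabulate no lag distribution). Exogenous
ABA multiplies the ER-lag median only (`lagMultiplierAba`, default slope
0.15 per µM — the dose–lag curve is not tabulated, so the slope is a free
configuration constant) and never touches TR, reproducing the observation
that ABA inhibits ER without affecting TR timing; cold delays both events
simply because temperature enters the thermal-time clock itself.

Dish-level reproducibility uses one root seed with fixed per-(temperature,
dish) offsets, so identical seeds give bit-identical datasets and adding
dishes never reshuffles earlier draws.

**Treatment rules** (`applyTreatment()`) encode the working model of
dormancy release: darkness blocks germination entirely; in water only the
non-dormant fraction `fNd` germinates; after-ripening or GA additionally
release the non-deep physiological dormancy layer `fNpd` (fluridone alone
is a no-op; combined with GA it adds a small increment, default 0.05); GA
plus ethylene plus nitrate release everything; scarification releases a
coat-release fraction (default 0.78) that may exceed the non-deep-PD level.

**Fixture calibration.** The packaged `FH_black_1` state uses
`fNd = 0.112`, `fNpd = 0.513`, `fDpd = 0.375`. These were calibrated once,
from the closed-form model, so that the simulated 14-day G$_{max}$ ladder
reproduces the published ladder (about 10% in water at 25 °C, about 60%
after-ripened, about 75% scarified, >90% fully released): a 14-day window
leaves about 4% of viable seeds unfinished at 24 °C (and about 10% at
25 °C) because slow-$\Theta$, low-ceiling seeds have not completed ER, so
the release fractions sit slightly above the printed percentages.
Similarly, the ceiling SDs are read *relatively* — 2.0 °C for black #1
("broad") versus 0.75 °C for brown #1 ("sharp") — because under
comonotonicity a much broader black ceiling would depress the 14-day
G$_{max}$ at 24 °C well below the printed ~60%. $\sigma_\Theta$ is 30 °C·d
(black #1), 25 (brown #1) and 15 (seedlot #2, "sharper distributions").

Each fixture carries its own 9-temperature grid. The sub-optimal range
(13–25 °C) is shared; the supra-optimal points are placed below each
population's ceiling, because a population with $T_c \approx 31$ °C and a
small SD produces no germination at 31 °C and above within the scoring
window — a single 10–34 °C grid cannot resolve the brown #1 ceiling.
Scoring runs daily to day 45 so that percentile times near the regime
boundaries are observable.

## The fitting pipeline

`fitThermalTime()` inverts the model in the classical two-stage way:

1. **Percentile times.** Replicate dishes are pooled per temperature; the
   cumulative percentage (of *sown* seeds) is monotonized by running
   maximum and the time to each percentile $g$ is linearly interpolated
   between bracketing scoring times (`interpolatePercentileTimes()`).
   Percentiles run 10, 20, … up to the largest multiple of 10 strictly
   below the observed maximum germination percentage, which also serves as
   the viable-fraction reference $G_{ref}$, making ranks $g/G_{ref}$
   quantiles within the viable population.
2. **Lag correction.** The pipeline fits ER (the germination event) by
   default. When TR was scored too, the median observed TR→ER gap across
   all (temperature, percentile) pairs is subtracted from the ER times
   first, so the thermal-time clock refers to the start of the rupture
   cascade instead of absorbing the lag into biased cardinal temperatures
   (`lagCorrection = FALSE` disables this; `event = "tr"` fits TR
   directly).
3. **Regime split.** Rates $GR_g(T) = 1/t_g(T)$ are split at the
   temperature with the maximal rate for the reference percentile
   (`splitRegimes()`, 50 or the lowest available). The shared peak
   temperature is genuinely ambiguous on a discrete grid: when it falls
   below the true optimum it belongs to the cold line, when above it is
   already ceiling-limited. Including it unconditionally in both
   regressions (the textbook tie-break, available as `peakRule = "both"`)
   biased both intercepts by 2–3 °C on these grids in closed-form
   analysis, so the default `peakRule = "consistency"` assigns it per
   percentile: the point joins the sub-optimal line only if its observed
   rate is within 10% of the extrapolated strictly-sub-optimal line, and
   the supra-optimal line otherwise.
4. **Per-percentile OLS.** Unweighted least squares per percentile in each
   regime (weighted variants deliberately omitted; the construction uses
   off-the-shelf linear regression). Sub-optimal: $\Theta_{cold}(g)$ is the
   reciprocal slope and $T_{base}$ the x-intercept of the reference (50th)
   percentile, with all intercepts kept as diagnostics. Supra-optimal:
   $T_c(g)$ is the x-intercept and $\theta_{warm}$ the negative reciprocal
   of the median slope. Percentiles with fewer than 3 usable temperatures
   in a regime are dropped from that regime; fewer than 3 temperatures, or
   fewer than 2 usable percentiles overall, is a hard error, not a warning.
5. **Probit distribution fits.** `fitThresholdDistribution()` regresses the
   per-percentile thresholds on $\Phi^{-1}(g/G_{ref})$: the intercept is
   the population median, the (sign-corrected) slope the SD. The plain SD
   of the per-percentile estimates is reported alongside as
   `sigmaThetaDispersion` / `sigmaTcDispersion`; the probit slope is the
   headline value. $T_{opt}$ is then the intersection of the two fitted
   median lines.

Degenerate inputs fail with stage-labelled messages: zero germination
(no percentile grid), fewer than 4 temperatures, flat or wrong-signed rate
profiles. A monotone increasing profile fits the sub-optimal regime only,
with `NA` ceiling slots and a warning.

## Dormancy decomposition, hormones, qPCR

`decomposeLayers()` converts a treatment-response G$_{max}$ table into layer
fractions by ratios against the full-release value, which is taken as the
viability ceiling (no viability staining is reported; >90% germination
under GA + ethylene + nitrate is treated as complete release). Both
normalizations — per viable seed and per sown seed (`ofTotal`) — are
reported, since "two-thirds of the population" can be read either way.
Scarification is surfaced only as a diagnostic ratio because coat removal
can release more than the non-deep-PD layer. Noise-induced negative
differences are clipped at zero with a recorded note; a release value below
the water control is an error.

The hormone module is deliberately descriptive and unit-agnostic (figure
axes' units are not restated): `bioactiveGA()` sums GA4 + GA7 + GA1 + GA3,
`pathwayPartition()` splits the 13-non-hydroxylated (GA15, GA24, GA9, GA4,
GA7) from the 13-hydroxylated (GA44, GA19, GA20, GA1, GA3) branch with GA12
excluded as the common precursor, and `gaAbaRatio()` tracks the bioactive
GA/ABA ratio and its fold-change against the dry seed. Catabolites such as
GA34/GA8 are not in the default vocabulary (the profiled species are the
listed ones) but the schema accepts extensions. Below-detection values are
encoded as zero; ABA reaching zero after imbibition yields an explicit
`Inf` ratio rather than an error.

The qPCR module accepts Cq values and per-gene amplification efficiencies
as *inputs* (raw-fluorescence efficiency estimation is out of scope).
Efficiencies are fractions with amplification factor $1+E$; factor-form
values (e.g. 1.9) are accepted via a switch. `relativeQuantity()` computes
$Q = (1+E)^{Cq_{min}-Cq}$, `geNormM()` the mean pairwise log-ratio SD
(cross-checked in the tests against a brute-force all-pairs oracle),
`selectReferences()` picks the two most stable genes with lexicographic tie
breaks, and `normalizeTargets()` divides by the per-sample geometric mean
of the references. Replicates are normalized individually and summarized
afterwards on the log scale (normalizing averaged Cq values instead is the
documented alternative); missing Cq values are excluded from the per-gene
minimum, never imputed.

## Worked example

```{r example}
params <- seedParamSet("black_AR_1")
params

design <- experimentDesign(fixtureTemperatures("black_AR_1"),
                           scoringTimes = fixtureScoringTimes(),
                           rngSeed = 2024)
records <- simulateExperiment(design, params)
fit <- fitThermalTime(records)
fit
```

```{r decompose}
decomposeLayers(water = 10, release = 60, full = 90)
```

## Problem sizes, numerical choices, limitations

The recovery experiments mirror the assay scale: 3 dishes × 30 seeds × 9
temperatures, daily scoring to day 45, with medians taken over 20
replicate experiments — small enough that a full recovery study runs in
seconds, large enough that the medians sit within ±1 °C of the generating
cardinal temperatures. The sampling spread of a single experiment's
estimates is several times larger; the acceptance machinery therefore
always reports medians.

What the simulator does *not* emulate: dormancy cycling across seasons,
hydrotime (water-potential) thresholds, mechanistic hormone kinetics,
seed-to-seed variation in $T_{base}$ or $\theta_{warm}$, dish effects, or
scoring error. Passing recovery tests therefore show that the inverse
pipeline is consistent with the forward model under realistic assay noise —
not that real seedlots satisfy the model's normality or comonotonicity
assumptions. The two-stage regression construction is the contract here; a
one-step maximum-likelihood fit of the full threshold model would use the
data more efficiently and is left as future work.
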