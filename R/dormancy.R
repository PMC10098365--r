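#' Maximum germination percentage from a time-course
#'
#' Mean across dishes of the final-scoring-time cumulative endosperm-rupture
#' percentage, with the between-dish standard error of the mean.  Records
#' spanning several temperatures are summarized per temperature.
#'
#' @param records germination records.
#' @param event `"er"` (default) or `"tr"`.
#' @return a data.frame with columns `temperature`, `gmax` (%), `sem`
#'   (`NA` for a single dish) and `nDishes`.
#' @examples
#' rec <- data.frame(dish = rep(c("a", "b", "c"), each = 2),
#'                   temperature_C = 24, time_d = rep(c(7, 14), 3),
#'                   tr_count = c(10, 18, 12, 18, 9, 18),
#'                   er_count = c(8, 18, 10, 18, 9, 18), dish_size = 30)
#' estimateGmax(rec)  # 60% at 24 degC
#' @export
estimateGmax <- function(records, event = c("er", "tr")) {
  event <- match.arg(event)
  validateGerminationRecords(records, integerCounts = FALSE)
  if (nrow(records) == 0L) stop("input error: no records")
  col <- if (event == "er") "er_count" else "tr_count"
  out <- lapply(split(records, records$temperature_C), function(r) {
    finals <- vapply(split(r, r$dish), function(d) {
      d <- d[order(d$time_d), ]
      100 * d[[col]][nrow(d)] / d$dish_size[nrow(d)]
    }, 0)
    data.frame(temperature = r$temperature_C[1], gmax = mean(finals),
               sem = if (length(finals) > 1) sd(finals) / sqrt(length(finals)) else NA_real_,
               nDishes = length(finals))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Decompose treatment-response G_max values into dormancy layers
#'
#' Given maximum germination percentages under water, a non-deep-PD
#' releasing treatment (after-ripening and/or GA) and the full-release
#' combination (GA + ethylene + nitrate), the viable fraction is the
#' full-release G_max/100 and the layer fractions follow by ratios:
#' `fNd = G_water / G_full`, `fNd + fNpd = G_release / G_full`,
#' `fDpd = 1 - G_release / G_full`.  When both after-ripening and GA entries
#' are supplied their maximum defines the releasable level.  Differences
#' made negative by sampling noise are clipped at zero with a recorded
#' warning; a release value below the water control beyond `tol` is an
#' inconsistency error, as is any partial-release value above full release.
#'
#' @param water G_max (%) in water.
#' @param release G_max (%) under after-ripening and/or GA; give one value
#'   or a vector (e.g. `c(AR = 58, GA = 61)`).
#' @param full G_max (%) under the full-release treatment.
#' @param scarified optional G_max (%) after coat removal; reported as a
#'   diagnostic ratio only (coat release can exceed non-deep-PD release).
#' @param tol tolerance (% points) for consistency checks.
#' @return a [DormancyDecomposition-class] object.  The `ofTotal` slot gives
#'   the same fractions per sown seed; a `scarifiedRatio` attribute is
#'   attached when `scarified` is supplied.
#' @examples
#' d <- decomposeLayers(water = 10, release = 60, full = 90)
#' fNpd(d) + fNd(d)  # 2/3 of the viable population
#' @export
decomposeLayers <- function(water, release, full, scarified = NULL, tol = 1e-6) {
  vals <- c(water = water, full = full, release)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 100))
    stop("G_max values must lie in [0, 100]")
  rel <- max(release)
  if (full <= 0) stop("full-release G_max must be positive")
  if (rel > full + tol || water > full + tol)
    stop("inconsistency error: partial-release G_max exceeds full-release G_max")
  if (rel < water - tol)
    stop("inconsistency error: release G_max below the water control")

  warn <- character()
  fnd <- water / full
  fndnpd <- min(rel, full) / full
  fnpd <- fndnpd - fnd
  fdpd <- 1 - fndnpd
  for (nm in c("fnpd", "fdpd")) {
    v <- get(nm)
    if (v < 0) {
      warn <- c(warn, sprintf("%s clipped from %.3g to 0 (sampling noise)", nm, v))
      assign(nm, 0)
    }
  }
  tot <- fnd + fnpd + fdpd
  obj <- new("DormancyDecomposition", fNd = fnd / tot, fNpd = fnpd / tot,
             fDpd = fdpd / tot, viableFraction = full / 100,
             ofTotal = c(fNd = fnd, fNpd = fnpd, fDpd = fdpd) / tot * full / 100,
             warnings = warn)
  if (!is.null(scarified)) attr(obj, "scarifiedRatio") <- scarified / full
  obj
}

#' Tidy contrasts of G_max (or fitted quantities) between seed states
#'
#' Pure reshaping convenience: pairwise differences and ratios of a named
#' set of values (e.g. freshly harvested vs after-ripened, black vs brown,
#' seedlot #1 vs #2).
#'
#' @param values a named numeric vector (names are state labels).
#' @param pairs optional 2-column matrix / data.frame of label pairs; default
#'   all unordered pairs.
#' @return a data.frame with columns `a`, `b`, `valueA`, `valueB`,
#'   `difference` (a - b) and `ratio` (a / b).
#' @examples
#' compareStates(c(FH_black = 10, AR_black = 60, brown = 60))
#' @export
compareStates <- function(values, pairs = NULL) {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("'values' must be fully named")
  if (is.null(pairs)) {
    cmb <- utils::combn(names(values), 2)
    pairs <- data.frame(a = cmb[1, ], b = cmb[2, ])
  } else {
    pairs <- as.data.frame(pairs)
    names(pairs) <- c("a", "b")
    bad <- setdiff(unique(c(pairs$a, pairs$b)), names(values))
    if (length(bad)) stop("mismatched labels: ", paste(bad, collapse = ", "))
  }
  data.frame(a = pairs$a, b = pairs$b,
             valueA = unname(values[pairs$a]), valueB = unname(values[pairs$b]),
             difference = unname(values[pairs$a] - values[pairs$b]),
             ratio = unname(values[pairs$a] / values[pairs$b]))
}
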