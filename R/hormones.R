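#' Recognized gibberellin and abscisic-acid pathway metabolites
#'
#' Column-name vocabulary of the hormone-profile tables: the bioactive
#' gibberellins (GA4, GA7 from the 13-non-hydroxylated branch; GA1, GA3 from
#' the 13-hydroxylated branch), their precursors on each branch, the common
#' precursor GA12, and ABA with its catabolites phaseic acid (PA) and
#' dihydrophaseic acid (DPA).
#'
#' @format Named character vectors.
#' @name hormone-vocabulary
#' @aliases bioactiveGaSpecies non13OHSpecies oh13Species recognizedMetabolites
NULL

#' @rdname hormone-vocabulary
#' @export
bioactiveGaSpecies <- c("GA4", "GA7", "GA1", "GA3")

#' @rdname hormone-vocabulary
#' @export
non13OHSpecies <- c("GA15", "GA24", "GA9", "GA4", "GA7")

#' @rdname hormone-vocabulary
#' @export
oh13Species <- c("GA44", "GA19", "GA20", "GA1", "GA3")

#' @rdname hormone-vocabulary
#' @export
recognizedMetabolites <- c("GA12", unique(c(non13OHSpecies, oh13Species)),
                           "ABA", "PA", "DPA")

#' Validate a hormone-profile table
#'
#' Wide-format table: one row per sample, metabolite contents in columns
#' named after [recognizedMetabolites] (mass-normalized amounts; the module
#' is unit-agnostic and ratio-based).  Contents must be non-negative;
#' below-detection values are encoded as 0 (keep a detection flag alongside
#' if provenance matters).  Unknown metabolite columns are rejected unless
#' whitelisted via `extra`.
#'
#' @param profile a data.frame; non-metabolite annotation columns (sample id,
#'   time, morph, ...) are allowed and ignored by the sums.
#' @param extra additional accepted metabolite column names.
#' @return the profile, invisibly.
#' @export
validateHormoneProfile <- function(profile, extra = character()) {
  stopifnot(is.data.frame(profile))
  known <- c(recognizedMetabolites, extra)
  gaLike <- grepl("^(GA[0-9]+|ABA|PA|DPA)$", names(profile))
  unknown <- setdiff(names(profile)[gaLike], known)
  if (length(unknown))
    stop("unknown metabolite column(s): ", paste(unknown, collapse = ", "),
         "; accepted names: ", paste(known, collapse = ", "))
  met <- intersect(names(profile), known)
  for (m in met) {
    v <- profile[[m]]
    if (!is.numeric(v) || any(is.finite(v) & v < 0))
      stop("negative or non-numeric content in column '", m, "'")
  }
  invisible(profile)
}

# Row-wise sum over the metabolite columns present, warning about absences.
.metaboliteSum <- function(profile, species, what) {
  present <- intersect(species, names(profile))
  absent <- setdiff(species, present)
  if (length(absent))
    warning(what, ": treating absent metabolite(s) as zero: ",
            paste(absent, collapse = ", "))
  if (!length(present)) return(rep(0, nrow(profile)))
  rowSums(as.data.frame(profile[present]), na.rm = TRUE)
}

#' Bioactive gibberellin content per sample
#'
#' Sum of GA4 + GA7 + GA1 + GA3; metabolites missing from the table are
#' treated as absent with a warning.
#'
#' @inheritParams validateHormoneProfile
#' @return numeric vector, one bioactive-GA sum per row of `profile`.
#' @examples
#' bioactiveGA(data.frame(GA4 = 1, GA7 = 1, GA1 = 1, GA3 = 1))  # 4
#' @export
bioactiveGA <- function(profile, extra = character()) {
  validateHormoneProfile(profile, extra)
  .metaboliteSum(profile, bioactiveGaSpecies, "bioactiveGA")
}

#' Partition GA metabolites into the two hydroxylation pathways
#'
#' Sums the 13-non-hydroxylated branch (GA15, GA24, GA9, GA4, GA7) and the
#' 13-hydroxylated branch (GA44, GA19, GA20, GA1, GA3); the common precursor
#' GA12 is excluded from both.  A dominance flag marks samples where the
#' non-13-OH branch carries the larger pool.
#'
#' @inheritParams validateHormoneProfile
#' @param warnAbsent warn about metabolites missing from the table.
#' @return a data.frame with columns `non13OH`, `oh13`,
#'   `non13OHDominant`.
#' @examples
#' p <- data.frame(GA15 = 1, GA24 = 1, GA9 = 1, GA4 = 1, GA7 = 1,
#'                 GA44 = 1, GA19 = 1, GA20 = 1, GA1 = 1, GA3 = 1)
#' pathwayPartition(p)  # 5 and 5
#' @export
pathwayPartition <- function(profile, extra = character(), warnAbsent = TRUE) {
  validateHormoneProfile(profile, extra)
  wrap <- if (warnAbsent) identity else suppressWarnings
  non13 <- wrap(.metaboliteSum(profile, non13OHSpecies, "pathwayPartition"))
  oh13 <- wrap(.metaboliteSum(profile, oh13Species, "pathwayPartition"))
  data.frame(non13OH = non13, oh13 = oh13, non13OHDominant = non13 > oh13)
}

#' GA/ABA ratios and fold-changes over an imbibition time-course
#'
#' Ratio of bioactive GA to ABA per sampling time, plus the fold-change of
#' the ratio relative to the dry seed (t = 0).  ABA falling to zero at a
#' later time yields an explicit `Inf` ratio, never an error; a missing dry
#' sample, or zero ABA in the dry sample, is a precondition error.
#'
#' @param profile wide hormone table with one row per sampling time.
#' @param timeCol name of the time column (default `"time_h"`).
#' @inheritParams validateHormoneProfile
#' @return a data.frame with columns `time`, `gaSum`, `aba`, `ratio`,
#'   `fold`.
#' @examples
#' p <- data.frame(time_h = c(0, 24), GA4 = c(1, 2), GA7 = 0, GA1 = 0,
#'                 GA3 = 0, ABA = c(4, 2))
#' gaAbaRatio(p)  # ratio doubles twice: fold = 4 at 24 h
#' @export
gaAbaRatio <- function(profile, timeCol = "time_h", extra = character()) {
  validateHormoneProfile(profile, extra)
  if (!timeCol %in% names(profile)) stop("time column '", timeCol, "' not found")
  if (!"ABA" %in% names(profile)) stop("an 'ABA' column is required")
  tm <- profile[[timeCol]]
  if (!any(tm == 0)) stop("missing dry sample: no row with ", timeCol, " == 0")
  ga <- suppressWarnings(bioactiveGA(profile, extra))
  aba <- profile$ABA
  if (any(aba[tm == 0] == 0)) stop("precondition error: ABA must be > 0 in the dry sample")
  ratio <- ifelse(aba > 0, ga / aba, Inf)
  ord <- order(tm)
  ratio0 <- ratio[tm == 0][1]
  data.frame(time = tm[ord], gaSum = ga[ord], aba = aba[ord],
             ratio = ratio[ord], fold = ratio[ord] / ratio0)
}
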