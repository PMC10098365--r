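#' Construct a Cq experiment
#'
#' @param cq numeric matrix of quantification cycles, genes in rows and
#'   samples in columns (a samples-by-genes matrix is accepted and
#'   transposed when row/column names make the orientation unambiguous via
#'   `genesInRows = FALSE`).  `NA` marks no amplification.
#' @param efficiency per-gene amplification efficiency.  With
#'   `efficiencyForm = "fraction"` (default) values are in `[0, 1]` and the
#'   amplification factor is `1 + E`; `"factor"` accepts the factor form
#'   (e.g. 1.9) directly.
#' @param genesInRows orientation of `cq`.
#' @param efficiencyForm `"fraction"` or `"factor"`.
#' @param colData optional sample annotation (data.frame).
#' @return a [CqExperiment-class] object.
#' @examples
#' cq <- matrix(c(20, 21, 22, 23, 25, 25.5, 26, 26.5), nrow = 2,
#'              byrow = TRUE, dimnames = list(c("ACT7", "CDC27B"), NULL))
#' CqExperiment(cq, efficiency = c(ACT7 = 0.95, CDC27B = 0.9))
#' @export
CqExperiment <- function(cq, efficiency, genesInRows = TRUE,
                         efficiencyForm = c("fraction", "factor"),
                         colData = NULL) {
  efficiencyForm <- match.arg(efficiencyForm)
  cq <- as.matrix(cq)
  if (!genesInRows) cq <- t(cq)
  if (is.null(rownames(cq))) stop("gene names are required")
  if (is.null(colnames(cq))) colnames(cq) <- paste0("sample", seq_len(ncol(cq)))
  if (!is.null(names(efficiency))) {
    miss <- setdiff(rownames(cq), names(efficiency))
    if (length(miss)) stop("missing efficiency for gene(s): ",
                           paste(miss, collapse = ", "))
    efficiency <- efficiency[rownames(cq)]
  } else if (length(efficiency) != nrow(cq)) {
    stop("missing efficiency: supply one value per gene")
  }
  if (efficiencyForm == "factor") efficiency <- efficiency - 1
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cq = cq),
    rowData = S4Vectors::DataFrame(efficiency = as.numeric(efficiency),
                                   row.names = rownames(cq)),
    colData = if (is.null(colData)) S4Vectors::DataFrame(row.names = colnames(cq))
              else S4Vectors::DataFrame(colData, row.names = colnames(cq)))
  new("CqExperiment", se)
}

#' Efficiency-corrected relative quantities
#'
#' Per gene j, `Q_ij = (1 + E_j) ^ (Cq_min,j - Cq_ij)`, so the sample with
#' the lowest Cq of each gene has Q = 1.  Missing Cq (no amplification) is
#' excluded from the per-gene minimum and propagates as `NA`.
#'
#' @param x a [CqExperiment-class] object, or a genes-by-samples Cq matrix
#'   together with `efficiency`.
#' @param efficiency per-gene efficiencies (fraction form) when `x` is a
#'   plain matrix.
#' @return matrix of relative quantities (genes x samples).
#' @examples
#' q <- relativeQuantity(matrix(c(20, 21), 1, 2,
#'                              dimnames = list("g", NULL)), efficiency = 1)
#' q  # 1 and 0.5: one cycle at perfect doubling halves the quantity
#' @export
relativeQuantity <- function(x, efficiency = NULL) {
  if (is(x, "CqExperiment")) {
    validObject(x)
    cq <- SummarizedExperiment::assay(x, "cq")
    eff <- SummarizedExperiment::rowData(x)$efficiency
  } else {
    cq <- as.matrix(x)
    if (is.null(efficiency)) stop("missing efficiency")
    eff <- rep_len(as.numeric(efficiency), nrow(cq))
  }
  qmat <- cq
  for (j in seq_len(nrow(cq))) {
    cmin <- min(cq[j, ], na.rm = TRUE)
    qmat[j, ] <- (1 + eff[j])^(cmin - cq[j, ])
  }
  qmat
}

#' geNorm expression-stability measure M
#'
#' For each gene j, M_j is the mean over all other genes k of the standard
#' deviation across samples of `log2(Q_j / Q_k)`.  A perfectly co-regulated
#' (constant-ratio) pair has M = 0; lower M means more stable expression.
#'
#' @param q matrix of relative quantities (genes x samples) from
#'   [relativeQuantity()], or a [CqExperiment-class] object.
#' @return named numeric vector of M values.
#' @export
geNormM <- function(q) {
  if (is(q, "CqExperiment")) q <- relativeQuantity(q)
  q <- as.matrix(q)
  if (nrow(q) < 2L || ncol(q) < 2L) stop("at least 2 genes and 2 samples are required")
  if (any(is.na(q))) stop("missing quantities: geNorm M requires complete Q values")
  if (any(q <= 0)) stop("zero or negative quantity: log-ratio undefined")
  lq <- log2(q)
  m <- vapply(seq_len(nrow(q)), function(j) {
    mean(vapply(setdiff(seq_len(nrow(q)), j),
                function(k) sd(lq[j, ] - lq[k, ]), 0))
  }, 0)
  names(m) <- rownames(q)
  m
}

#' Select the most stable reference genes
#'
#' The `k` genes with the lowest M values; ties are broken lexicographically
#' by gene id, making the selection deterministic.
#'
#' @param m named M-value vector from [geNormM()].
#' @param k number of references (default 2).
#' @return character vector of `k` gene ids.
#' @export
selectReferences <- function(m, k = 2) {
  if (k > length(m)) stop("k exceeds the number of scored genes")
  ord <- order(m, names(m))
  names(m)[ord][seq_len(k)]
}

#' Pairwise-variation series V(n/n+1)
#'
#' For the stability ranking, V(n/n+1) is the SD across samples of
#' `log2(NF_n / NF_(n+1))`, where NF_n is the geometric mean of the top-n
#' ranked genes per sample.  Reported for diagnostics; the reference count
#' is fixed at `k` by [selectReferences()].
#'
#' @param q relative-quantity matrix (genes x samples).
#' @param ranking gene ids from most to least stable.
#' @return named numeric vector `V2/3`, `V3/4`, ...
#' @export
pairwiseVariation <- function(q, ranking) {
  q <- as.matrix(q)
  if (length(ranking) < 3L) return(setNames(numeric(0), character(0)))
  nf <- function(n) apply(q[ranking[seq_len(n)], , drop = FALSE], 2,
                          function(col) exp(mean(log(col))))
  v <- vapply(2:(length(ranking) - 1L),
              function(n) sd(log2(nf(n) / nf(n + 1L))), 0)
  names(v) <- paste0("V", 2:(length(ranking) - 1L), "/", 3:length(ranking))
  v
}

#' geNorm stability report with reference selection
#'
#' @param x a [CqExperiment-class] object or relative-quantity matrix.
#' @param k number of references to select (default 2).
#' @return a [StabilityReport-class] object.
#' @examples
#' q <- rbind(stable1 = c(1, .5, .25, .8), stable2 = c(.9, .45, .225, .72),
#'            wobbly = c(1, .1, .9, .2))
#' genormReport(q)
#' @export
genormReport <- function(x, k = 2) {
  q <- if (is(x, "CqExperiment")) relativeQuantity(x) else as.matrix(x)
  m <- geNormM(q)
  ranking <- names(m)[order(m, names(m))]
  new("StabilityReport", mValues = m, ranking = ranking,
      references = selectReferences(m, k),
      pairwiseVariation = pairwiseVariation(q, ranking))
}

#' Normalize target genes against reference genes
#'
#' Divides each sample's quantities by the geometric mean of the reference
#' genes' quantities in that sample (per-replicate normalization; replicate
#' summaries are taken afterwards, as geometric mean +/- SEM on the log
#' scale).
#'
#' @param q relative-quantity matrix (genes x samples) or a
#'   [CqExperiment-class] object.
#' @param references reference gene ids (subset of the rownames).
#' @return matrix of normalized expression values (genes x samples).
#' @examples
#' q <- rbind(ref1 = c(0.25, 1), ref2 = c(1, 1), target = c(0.5, 2))
#' normalizeTargets(q, c("ref1", "ref2"))["target", ]
#' @export
normalizeTargets <- function(q, references) {
  if (is(q, "CqExperiment")) q <- relativeQuantity(q)
  q <- as.matrix(q)
  bad <- setdiff(references, rownames(q))
  if (length(bad)) stop("reference gene(s) not in the matrix: ",
                        paste(bad, collapse = ", "))
  refQ <- q[references, , drop = FALSE]
  if (any(is.na(refQ)) || any(refQ <= 0))
    stop("zero or missing reference quantity: normalization undefined")
  nf <- apply(refQ, 2, function(col) exp(mean(log(col))))
  sweep(q, 2, nf, `/`)
}
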