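#' High-confidence tissue ROI from a probability map
#'
#' @param tissueProb 3D array of tissue probabilities in [0, 1].
#' @param threshold inclusion threshold (inclusive), default 0.9.
#' @return logical 3D mask; warns when empty.
#' @export
tissueROIMask <- function(tissueProb, threshold = 0.9) {
  if (anyNA(tissueProb) || any(tissueProb < 0 | tissueProb > 1))
    stop("tissue probabilities must lie in [0, 1]")
  mask <- tissueProb >= threshold
  if (!any(mask))
    warning("tissue ROI is empty at this threshold")
  mask
}

#' ROI statistics of an rCBF map
#'
#' Mean and standard deviation (n - 1 denominator) of an rCBF map over a
#' region of interest. Voxels outside the map's quantified mask and
#' invalid-flagged (NA) voxels are excluded; the reported voxel count makes
#' the exclusion auditable.
#'
#' @param map an \linkS4class{RCBFMap}.
#' @param roi logical 3D mask.
#' @param tissue label recorded in the result (e.g. \code{"GM"}).
#' @return one-row data.frame with columns tissue, method, mean, sd,
#'   nVoxels; \code{NULL} (with a warning) when the intersection is empty.
#' @export
roiStats <- function(map, roi, tissue = NA_character_) {
  if (!identical(dim(roi), dim(map@values)))
    stop("ROI dimensions must match the map")
  sel <- roi & map@mask & is.finite(map@values)
  if (!any(sel)) {
    warning("empty ROI/map intersection; result suppressed")
    return(NULL)
  }
  v <- map@values[sel]
  data.frame(tissue = tissue, method = map@method, mean = mean(v),
    sd = if (length(v) > 1L) stats::sd(v) else 0, nVoxels = length(v),
    stringsAsFactors = FALSE)
}

#' Jensen-Shannon divergence between two samples
#'
#' Histograms both samples on shared bin edges, normalizes to probability
#' vectors P and Q, and returns
#' \eqn{JSD = \frac12 KL(P\|M) + \frac12 KL(Q\|M)} with \eqn{M = (P+Q)/2}
#' and base-2 logarithms, so the result lies in [0, 1]: 0 for identical
#' binned distributions, 1 for disjoint support. Empty bins contribute zero
#' by the 0 log 0 = 0 convention; values outside the edge range are clipped
#' into the outermost bins.
#'
#' @param valuesA,valuesB non-empty numeric samples.
#' @param binEdges strictly increasing bin edges; the default covers the
#'   physiological rCBF range 0-150 mL/100 g/min in 64 equal bins.
#' @return dimensionless divergence in [0, 1].
#' @examples
#' jsd(c(0.5, 0.5), c(0.5, 1.5), binEdges = c(0, 1, 2))  # ~0.3113
#' @export
jsd <- function(valuesA, valuesB, binEdges = seq(0, 150, length.out = 65)) {
  if (!length(valuesA) || !length(valuesB))
    stop("both samples must be non-empty")
  valuesA <- valuesA[is.finite(valuesA)]
  valuesB <- valuesB[is.finite(valuesB)]
  if (!length(valuesA) || !length(valuesB))
    stop("both samples must contain finite values")
  if (length(binEdges) < 3L || any(diff(binEdges) <= 0))
    stop("binEdges must be strictly increasing with at least two bins")
  nb <- length(binEdges) - 1L
  toP <- function(x) {
    x <- clamp(x, binEdges[1L], binEdges[length(binEdges)])
    idx <- findInterval(x, binEdges, rightmost.closed = TRUE,
      all.inside = TRUE)
    tabulate(idx, nbins = nb) / length(x)
  }
  P <- toP(valuesA); Q <- toP(valuesB)
  M <- (P + Q) / 2
  kl <- function(p, m) sum(ifelse(p > 0, p * log2(p / m), 0))
  0.5 * kl(P, M) + 0.5 * kl(Q, M)
}

#' Bland-Altman agreement analysis
#'
#' Differences d = x - y between paired per-subject measurements; bias is
#' their mean and the 95% limits of agreement are bias +/- 1.96 times their
#' standard deviation (n - 1 denominator).
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list with \code{bias}, \code{loaLow}, \code{loaHigh},
#'   \code{sdDiff} and \code{n}.
#' @export
blandAltman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s,
    sdDiff = s, n = length(x))
}

#' Spearman rank correlation
#'
#' Rank-based correlation with average ranks for ties and a two-sided p
#' value from \code{stats::cor.test}. Constant input has undefined rank
#' correlation and yields \code{rho = NA} with a warning.
#'
#' @param x,y paired numeric vectors of equal length >= 3.
#' @return list with \code{rho}, \code{p} and \code{n}.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman's rho is undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Compare the three gradient schemes on a per-subject metric
#'
#' Friedman's rank test across the three schemes (within-subject ranks),
#' followed by the three pairwise Wilcoxon signed-rank tests with Bonferroni
#' correction (factor 3). Subjects with any missing entry are excluded
#' listwise with a warning.
#'
#' @param metric numeric matrix, subjects x 3 schemes (column names are
#'   used as scheme labels when present).
#' @return list with \code{friedman} (statistic, df, p, n) and
#'   \code{pairwise} (data.frame: pair, p, pAdjusted).
#' @export
compareSchemes <- function(metric) {
  metric <- as.matrix(metric)
  if (ncol(metric) != 3L) stop("exactly 3 scheme columns are required")
  keep <- stats::complete.cases(metric)
  if (!all(keep)) {
    warning(sprintf("%d subject(s) excluded listwise for missing entries",
      sum(!keep)))
    metric <- metric[keep, , drop = FALSE]
  }
  if (nrow(metric) < 5L) stop("need at least 5 complete subjects")
  labels <- colnames(metric)
  if (is.null(labels)) labels <- c("2nd-mc", "1st-mc", "non-mc")
  fr <- stats::friedman.test(metric)
  # fully tied data: the tie-corrected statistic is 0/0; no evidence of any
  # scheme difference, so report a zero statistic
  if (is.nan(fr$statistic)) {
    fr$statistic[] <- 0
    fr$p.value <- 1
  }
  pairs <- utils::combn(3L, 2L)
  pw <- data.frame(
    pair = apply(pairs, 2L, function(ij)
      paste(labels[ij[1L]], labels[ij[2L]], sep = " vs ")),
    p = apply(pairs, 2L, function(ij)
      suppressWarnings(stats::wilcox.test(metric[, ij[1L]], metric[, ij[2L]],
        paired = TRUE, exact = FALSE)$p.value)),
    stringsAsFactors = FALSE)
  pw$pAdjusted <- pmin(1, pw$p * 3)
  list(friedman = list(statistic = unname(fr$statistic),
    df = unname(fr$parameter), p = fr$p.value, n = nrow(metric)),
    pairwise = pw)
}
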