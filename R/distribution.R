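# Equal-count binning of valid voxels by ascending map value, per-bin tissue
# composition ("distribution graph"), slope statistics, group averaging, bin
# contrasts, curve correlations, and spatial quantile-mask export.

#' Rank valid voxels and bin into equal-count bins
#'
#' Valid voxels are sorted ascending by map value (stable sort: ties resolved
#' by linear voxel index, x-fastest) and split into \code{nBins} bins of equal
#' count; when the count does not divide evenly, the remainder voxels go to
#' the lowest-index bins.
#'
#' @param valueMap 3D numeric array (e.g. maxcc or ALFF values).
#' @param valid 3D logical array of voxels to rank.
#' @param nBins number of bins (default 10).
#' @return A [BinAssignment-class].
#' @export
rankAndBin <- function(valueMap, valid, nBins = 10L) {
  checkSameGrid(valueMap, valid, "value map and validity mask")
  nBins <- as.integer(nBins)
  idx <- which(valid)
  nv <- length(idx)
  if (nv < nBins)
    stopWith("insufficient_voxels", "%d valid voxels cannot fill %d bins", nv, nBins)
  vals <- valueMap[idx]
  ord <- order(vals, method = "radix")  # stable: ties keep ascending voxel index
  base <- nv %/% nBins
  sizes <- base + as.integer(seq_len(nBins) <= nv %% nBins)
  binOfSorted <- rep.int(seq_len(nBins), sizes)
  binIndex <- array(0L, dim(valueMap))
  binIndex[idx[ord]] <- binOfSorted
  sortedVals <- vals[ord]
  edges <- if (nBins > 1L) sortedVals[cumsum(sizes)[-nBins]] else numeric(0)
  new("BinAssignment", binIndex = binIndex, nBins = nBins,
      binEdges = edges, nValid = nv)
}

# Exclusive voxel labels in the table's column order.
exclusiveLabels <- function(masks) {
  lab <- array("other", dim(brainMask(masks)))
  lab[maskArray(masks, "csf")] <- "CSF"
  lab[maskArray(masks, "wm")] <- "WM"
  lab[maskArray(masks, "gm")] <- "GM"
  lab[maskArray(masks, "va")] <- "VA"   # vessel mask takes precedence
  lab
}

#' Per-bin tissue composition of the valid voxels
#'
#' Entry (b, c) is the fraction of bin b's voxels carrying exclusive tissue
#' label c; voxels in no tissue class count as "other". Rows sum to 1.
#'
#' @param bins a [BinAssignment-class].
#' @param masks a [TissueMasks-class] on the same grid.
#' @param subjectId,sourceMap provenance labels ("maxcc", "alff", "maxcc_swap").
#' @return A [DistributionTable-class].
#' @export
binTissueFractions <- function(bins, masks, subjectId = "subject",
                               sourceMap = "maxcc") {
  checkSameGrid(bins@binIndex, brainMask(masks), "bin assignment and masks")
  lab <- exclusiveLabels(masks)
  sel <- bins@binIndex > 0L
  classes <- c("GM", "WM", "CSF", "VA", "other")
  counts <- table(factor(bins@binIndex[sel], levels = seq_len(bins@nBins)),
                  factor(lab[sel], levels = classes))
  fr <- unclass(counts / rowSums(counts))
  dimnames(fr) <- list(NULL, classes)
  new("DistributionTable", fractions = fr, subjectId = subjectId,
      sourceMap = sourceMap)
}

#' Ordinary-least-squares slope of a tissue's distribution curve
#'
#' Fits fraction ~ bin index (1..nBins) by OLS for one tissue class.
#'
#' @param table a [DistributionTable-class].
#' @param tissue one of "GM", "WM", "CSF", "VA", "other".
#' @return data.frame with columns tissue, slope, intercept, stderr, subjectId.
#' @export
fitDistributionSlope <- function(table, tissue) {
  tissue <- match.arg(tissue, colnames(table@fractions))
  y <- table@fractions[, tissue]
  if (length(y) < 3L) stopWith("parameter", "need at least 3 bins to fit a slope")
  x <- seq_along(y)
  fit <- lm(y ~ x)
  # slope standard error from the residuals directly: summary.lm warns on the
  # exact fits that degenerate tables legitimately produce
  se <- sqrt(sum(fit$residuals^2) / (length(y) - 2) / sum((x - mean(x))^2))
  data.frame(tissue = tissue, slope = unname(coef(fit)[2]),
             intercept = unname(coef(fit)[1]),
             stderr = se, subjectId = table@subjectId,
             stringsAsFactors = FALSE)
}

#' Average distribution tables across subjects
#'
#' Entrywise mean and sample standard deviation (n - 1 denominator).
#'
#' @param tables list of [DistributionTable-class] with one shape.
#' @return A [GroupDistribution-class].
#' @export
averageDistributions <- function(tables) {
  if (length(tables) < 2L)
    stopWith("degenerate", "need at least 2 tables (sd is undefined for n < 2)")
  dims <- lapply(tables, function(t) dim(t@fractions))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stopWith("shape", "all tables must share one shape")
  arr <- simplify2array(lapply(tables, fractions))  # nBins x class x subject
  mn <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), sd)
  mn <- mn / rowSums(mn)  # guard against accumulated rounding
  new("GroupDistribution", meanFractions = mn, sdFractions = sdv,
      nSubjects = length(tables))
}

# One- and two-sample t machinery with explicit degenerate handling:
# zero-variance samples return t = 0, p = 1 when the means agree and p = 0
# otherwise, flagged, rather than raising.
oneSampleT <- function(x, mu = 0) {
  n <- length(x)
  if (n < 2L) stopWith("parameter", "need at least 2 observations")
  if (sd(x) == 0) {
    hit <- isTRUE(all.equal(mean(x), mu))
    return(list(t = if (hit) 0 else sign(mean(x) - mu) * Inf,
                p = if (hit) 1 else 0, degenerate = TRUE, n = n))
  }
  tt <- t.test(x, mu = mu)
  list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE, n = n)
}

twoSampleT <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stopWith("parameter", "each sample needs at least 2 observations")
  sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  if (sp == 0) {
    hit <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (hit) 0 else sign(mean(x) - mean(y)) * Inf,
                p = if (hit) 1 else 0, degenerate = TRUE,
                n = c(length(x), length(y))))
  }
  tt <- t.test(x, y, var.equal = TRUE)  # pooled-variance form
  list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE,
       n = c(length(x), length(y)))
}

slopeVector <- function(slopes) {
  if (is.data.frame(slopes)) slopes$slope else as.numeric(slopes)
}

#' One-sample t-test of subject slopes against zero
#'
#' @param slopes numeric vector of per-subject slopes, or a data.frame with a
#'   \code{slope} column as returned by [fitDistributionSlope()].
#' @return List with elements t, p, degenerate, n.
#' @export
testSlopeNonzero <- function(slopes) oneSampleT(slopeVector(slopes), mu = 0)

#' Two-sample (pooled-variance) t-test between two slope sets
#'
#' @param slopesA,slopesB numeric vectors or data.frames with a \code{slope}
#'   column.
#' @return List with elements t, p, degenerate, n.
#' @export
compareSlopeSets <- function(slopesA, slopesB)
  twoSampleT(slopeVector(slopesA), slopeVector(slopesB))

#' Two-sample t-test between two bins' tissue fractions across subjects
#'
#' @param tables list of per-subject [DistributionTable-class].
#' @param tissue tissue class name.
#' @param binA,binB bin indices to contrast (e.g. 10 vs 9).
#' @return List with elements t, p, degenerate, n.
#' @export
compareBins <- function(tables, tissue, binA, binB) {
  nb <- nrow(tables[[1]]@fractions)
  if (binA < 1L || binA > nb || binB < 1L || binB > nb)
    stopWith("parameter", "bin indices must lie in 1..%d", nb)
  xa <- vapply(tables, function(t) t@fractions[binA, tissue], 0)
  xb <- vapply(tables, function(t) t@fractions[binB, tissue], 0)
  twoSampleT(xa, xb)
}

curveOf <- function(x, tissue) {
  f <- if (is(x, "GroupDistribution")) x@meanFractions else x@fractions
  f[, tissue]
}

#' Pearson correlation between two tissue distribution curves
#'
#' @param tableA,tableB [DistributionTable-class] or [GroupDistribution-class]
#'   objects with the same number of bins.
#' @param tissue tissue class name.
#' @return Pearson correlation of the two fraction-vs-bin curves.
#' @export
curveCorrelation <- function(tableA, tableB, tissue) {
  a <- curveOf(tableA, tissue); b <- curveOf(tableB, tissue)
  if (length(a) != length(b)) stopWith("shape", "curves have different bin counts")
  cor(a, b)
}

#' Export spatial quantile masks
#'
#' Groups consecutive bins into disjoint binary masks whose union is the valid
#' mask (e.g. 10 bins in groups of 2 give five 20\%-quantile masks).
#'
#' @param bins a [BinAssignment-class].
#' @param groupSize bins per mask; must divide \code{nBins}.
#' @return List of 3D logical arrays, lowest quantile first.
#' @export
exportQuantileMasks <- function(bins, groupSize = 2L) {
  if (bins@nBins %% groupSize != 0L)
    stopWith("parameter", "groupSize (%d) must divide nBins (%d)",
             groupSize, bins@nBins)
  lapply(seq_len(bins@nBins %/% groupSize), function(k) {
    lo <- (k - 1L) * groupSize + 1L
    bins@binIndex >= lo & bins@binIndex <= lo + groupSize - 1L
  })
}
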