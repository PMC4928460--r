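# Voxelwise maximum lagged cross-correlation against the seed regressor.
#
# The lag grid is integer multiples of the TR with |lag| <= the window
# half-width. Per lag, Pearson correlation is computed on the overlapping
# (truncated, not wrapped) segment, re-standardized per lag. Sign convention:
# lag > 0 means the voxel timecourse is delayed relative to the seed,
# i.e. voxel(t) ~ seed(t - lag).

lagGrid <- function(trSeconds, lagLimitS) {
  kMax <- floor(lagLimitS / trSeconds + 1e-9)
  (-kMax):kMax
}

# Overlap index ranges for shift k: compare seed[sIdx] with voxel[vIdx].
lagSlices <- function(n, k) {
  if (k >= 0) list(s = 1:(n - k), v = (1 + k):n)
  else list(s = (1 - k):n, v = 1:(n + k))
}

#' Lagged Pearson correlation between two timecourses
#'
#' For each integer shift k with |k * TR| <= \code{lagLimitS}, computes the
#' Pearson correlation on the overlapping n - |k| samples. A zero-variance
#' overlap segment yields r = 0 with a degenerate flag rather than an error.
#'
#' @param seed,voxel numeric timecourses of equal length.
#' @param trSeconds sampling interval in seconds.
#' @param lagLimitS lag window half-width in seconds (default 6).
#' @return data.frame with columns \code{lagS}, \code{r}, \code{degenerate}.
#' @export
laggedPearson <- function(seed, voxel, trSeconds, lagLimitS = 6.0) {
  n <- length(seed)
  if (length(voxel) != n)
    stopWith("shape", "seed (%d) and voxel (%d) lengths differ", n, length(voxel))
  ks <- lagGrid(trSeconds, lagLimitS)
  if (n - max(abs(ks)) < 10L)
    stopWith("invalid_length",
             "need at least 10 overlapping samples at the widest lag")
  out <- lapply(ks, function(k) {
    sl <- lagSlices(n, k)
    s <- seed[sl$s]; v <- voxel[sl$v]
    if (sd(s) == 0 || sd(v) == 0)
      data.frame(lagS = k * trSeconds, r = 0, degenerate = TRUE)
    else
      data.frame(lagS = k * trSeconds, r = cor(s, v), degenerate = FALSE)
  })
  do.call(rbind, out)
}

#' Maximum of a lagged-correlation profile
#'
#' Returns the (maxcc, lag) pair with the largest correlation. Ties are broken
#' by smallest |lag|, then by the negative lag first.
#'
#' @param pairs data.frame with columns \code{lagS} and \code{r}, as returned
#'   by [laggedPearson()].
#' @return List with elements \code{maxcc} and \code{lagS}.
#' @export
maxCorrelation <- function(pairs) {
  if (!nrow(pairs)) stopWith("empty", "no (lag, r) pairs supplied")
  ord <- order(-pairs$r, abs(pairs$lagS), pairs$lagS)
  list(maxcc = pairs$r[ord[1]], lagS = pairs$lagS[ord[1]])
}

#' Voxelwise maximum lagged-correlation (maxcc) map
#'
#' Applies [laggedPearson()] + [maxCorrelation()] to every brain voxel against
#' the seed regressor and flags as valid the voxels whose maximum correlation
#' strictly exceeds the threshold (with the optimal lag inside the window by
#' construction). Voxels outside the brain mask are invalid with undefined
#' maxcc and lag. Zero-variance voxels are invalid, never an error.
#'
#' @param series a [BoldSeries-class], band-pass filtered upstream.
#' @param seed a [SeedTimecourse-class] with the same TR and length.
#' @param brainMask 3D logical array on the series grid.
#' @param threshold minimum correlation for validity (strict, default 0.3).
#' @param lagLimitS lag window half-width in seconds (default 6).
#' @param verbose message the valid-voxel count (default FALSE).
#' @return A [LagCorrelationMap-class].
#' @export
computeMaxccMap <- function(series, seed, brainMask, threshold = 0.3,
                            lagLimitS = 6.0, verbose = FALSE) {
  if (abs(series@trSeconds - seed@trSeconds) > 1e-9)
    stopWith("sampling", "series TR (%g s) and seed TR (%g s) differ",
             series@trSeconds, seed@trSeconds)
  d <- dim(series@data)
  n <- d[4]
  if (length(seed@values) != n)
    stopWith("shape", "seed length (%d) differs from series timepoints (%d)",
             length(seed@values), n)
  checkSameGrid(series@data, brainMask, "series and brain mask")

  idx <- which(brainMask)
  X <- t(asVoxelMatrix(series@data)[idx, , drop = FALSE])  # time x voxel
  ks <- lagGrid(series@trSeconds, lagLimitS)
  if (n - max(abs(ks)) < 10L)
    stopWith("invalid_length",
             "need at least 10 overlapping samples at the widest lag")
  s <- seed@values

  nb <- length(idx)
  bestR <- rep(-Inf, nb)
  bestK <- integer(nb)
  # scan lags in tie-break priority (smallest |lag| first, negative before
  # positive); a strictly larger r is required to displace the incumbent
  for (k in ks[order(abs(ks), ks)]) {
    sl <- lagSlices(n, k)
    sc <- s[sl$s] - mean(s[sl$s])
    ss <- sum(sc^2)
    V <- X[sl$v, , drop = FALSE]
    m <- length(sl$v)
    cs <- colSums(V)
    vv <- colSums(V^2) - cs^2 / m
    den <- sqrt(ss * vv)
    r <- as.numeric(crossprod(sc, V))
    r <- ifelse(den > 0, r / den, 0)
    upd <- r > bestR
    bestR[upd] <- r[upd]
    bestK[upd] <- k
  }
  bestR <- pmin(pmax(bestR, -1), 1)

  maxcc <- array(NA_real_, d[1:3]); maxcc[idx] <- bestR
  lagS <- array(NA_real_, d[1:3]); lagS[idx] <- bestK * series@trSeconds
  valid <- array(FALSE, d[1:3]); valid[idx] <- bestR > threshold
  if (verbose)
    message(sprintf("maxcc map '%s': %d of %d brain voxels valid (threshold %g)",
                    series@subjectId, sum(valid), nb, threshold))
  new("LagCorrelationMap", maxcc = maxcc, lagS = lagS, valid = valid,
      threshold = threshold, lagLimitS = lagLimitS,
      trSeconds = series@trSeconds, subjectId = series@subjectId,
      seedLabel = seed@sourceLabel)
}
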