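# ALFF: per-voxel amplitude of low-frequency fluctuation. Each demeaned voxel
# timecourse is Fourier transformed; the one-sided amplitude spectrum
# A_j = 2|X_j|/n (no doubling at the Nyquist bin for even n) is summed over the
# bins falling inside the band, endpoints inclusive. With this convention a
# unit-amplitude cosine sitting exactly on an in-band bin yields ALFF = 1.
# No window taper is applied: the input is already band-passed. The map is not
# divided by its global mean; all downstream statistics are rank-based, so any
# fixed amplitude convention leaves them unchanged.

#' Compute an ALFF map
#'
#' @param series a [BoldSeries-class], preprocessed upstream.
#' @param brainMask 3D logical array; voxels outside are NA in the result.
#' @param lowHz,highHz band edges in Hz (defaults 0.01 and 0.15), endpoints
#'   inclusive; \code{highHz} must not exceed the Nyquist frequency.
#' @return An [AlffMap-class].
#' @export
computeAlff <- function(series, brainMask, lowHz = 0.01, highHz = 0.15) {
  d <- dim(series@data)
  n <- d[4]
  tr <- series@trSeconds
  if (highHz > nyquistHz(tr) + 1e-12)
    stopWith("invalid_band", "highHz (%g) exceeds the Nyquist frequency (%g)",
             highHz, nyquistHz(tr))
  checkSameGrid(series@data, brainMask, "series and brain mask")

  j <- seq_len(floor(n / 2))           # positive-frequency bins
  fj <- j / (n * tr)
  inBand <- fj >= lowHz - 1e-12 & fj <= highHz + 1e-12
  if (!any(inBand))
    stopWith("no_bins", "no frequency bin falls inside [%g, %g] Hz at n=%d, TR=%g",
             lowHz, highHz, n, tr)

  idx <- which(brainMask)
  X <- t(asVoxelMatrix(series@data)[idx, , drop = FALSE])
  X <- sweep(X, 2, colMeans(X))
  A <- Mod(mvfft(X)[j + 1L, , drop = FALSE]) * (2 / n)
  if (n %% 2L == 0L) A[length(j), ] <- A[length(j), ] / 2  # Nyquist: one-sided already
  alffVals <- colSums(A[inBand, , drop = FALSE])

  alff <- array(NA_real_, d[1:3])
  alff[idx] <- alffVals
  new("AlffMap", alff = alff, band = c(lowHz, highHz), subjectId = series@subjectId)
}
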