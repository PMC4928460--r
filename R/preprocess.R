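# Temporal band-pass filtering (zero-phase Butterworth) and spatial Gaussian
# smoothing. The IIR filter runs forward and backward with odd-reflection edge
# padding and steady-state initial conditions, applied to all voxel columns at
# once so whole 4D series filter in a few vectorized passes.

butterCoefs <- function(lowHz, highHz, order, trSeconds) {
  checkBand(lowHz, highHz, trSeconds)
  flt <- signal::butter(order, c(lowHz, highHz) * 2 * trSeconds, type = "pass")
  list(b = flt$b, a = flt$a)
}

# Steady-state unit-step filter state (direct form II transposed), so that a
# constant input produces a constant output with no start-up transient.
filterSteadyState <- function(b, a) {
  m <- max(length(a), length(b)) - 1L
  a <- c(a, rep(0, m + 1L - length(a)))
  b <- c(b, rep(0, m + 1L - length(b)))
  comp <- matrix(0, m, m)  # companion matrix of the monic denominator
  comp[1, ] <- -a[-1] / a[1]
  if (m > 1) comp[cbind(2:m, 1:(m - 1))] <- 1
  solve(diag(m) - t(comp), b[-1] - a[-1] * b[1])
}

# One IIR pass over the rows of X (time down the rows), all columns at once.
iirFilterMatrix <- function(b, a, X, Zinit) {
  m <- length(a) - 1L
  Z <- Zinit
  Y <- matrix(0, nrow(X), ncol(X))
  for (t in seq_len(nrow(X))) {
    xt <- X[t, ]
    yt <- b[1] * xt + Z[1, ]
    if (m > 1L)
      for (k in seq_len(m - 1L)) Z[k, ] <- b[k + 1L] * xt - a[k + 1L] * yt + Z[k + 1L, ]
    Z[m, ] <- b[m + 1L] * xt - a[m + 1L] * yt
    Y[t, ] <- yt
  }
  Y
}

# Forward-backward (zero-phase) filtering of each column of X with
# odd-reflection padding of `padlen` samples at both ends.
filtfiltMatrix <- function(b, a, X, padlen) {
  n <- nrow(X)
  if (n <= max(padlen, 3L * (length(a) - 1L)))
    stopWith("invalid_length",
             "series of length %d is too short for an order-%d zero-phase filter",
             n, length(a) - 1L)
  top <- 2 * rep(1, padlen) %o% X[1, ] - X[(padlen + 1L):2L, , drop = FALSE]
  bot <- 2 * rep(1, padlen) %o% X[n, ] - X[(n - 1L):(n - padlen), , drop = FALSE]
  ext <- rbind(top, X, bot)
  zi <- filterSteadyState(b, a)
  Y <- iirFilterMatrix(b, a, ext, zi %o% ext[1, ])
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y <- iirFilterMatrix(b, a, Y, zi %o% Y[1, ])
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y[(padlen + 1L):(padlen + n), , drop = FALSE]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to each voxel
#' timecourse. The two passes square the magnitude response and cancel the
#' phase, so an in-band sinusoid keeps its frequency and timing. Edge effects
#' are controlled by odd-reflection padding (3 x order samples) and
#' steady-state initial conditions.
#'
#' @param x a [BoldSeries-class] or a numeric timecourse.
#' @param lowHz,highHz band edges in Hz; 0 < low < high < Nyquist.
#' @param order filter order (default 3).
#' @param trSeconds sampling interval; only needed for numeric input (a
#'   \code{BoldSeries} carries its own TR).
#' @return Filtered object of the same shape as the input.
#' @examples
#' tr <- 0.72; t <- (0:499) * tr
#' y <- bandpassFilter(sin(2 * pi * 0.05 * t), 0.01, 0.15, trSeconds = tr)
#' @export
setGeneric("bandpassFilter",
  function(x, lowHz = 0.01, highHz = 0.15, order = 3L, trSeconds = NULL)
    standardGeneric("bandpassFilter"))

#' @rdname bandpassFilter
setMethod("bandpassFilter", "numeric",
  function(x, lowHz, highHz, order, trSeconds) {
    if (is.null(trSeconds)) stopWith("parameter", "trSeconds is required for numeric input")
    cf <- butterCoefs(lowHz, highHz, order, trSeconds)
    as.numeric(filtfiltMatrix(cf$b, cf$a, matrix(x, ncol = 1), 3L * as.integer(order)))
  })

#' @rdname bandpassFilter
setMethod("bandpassFilter", "BoldSeries",
  function(x, lowHz, highHz, order, trSeconds) {
    cf <- butterCoefs(lowHz, highHz, order, x@trSeconds)
    d <- dim(x@data)
    M <- t(asVoxelMatrix(x@data))                 # time x voxel
    M <- filtfiltMatrix(cf$b, cf$a, M, 3L * as.integer(order))
    BoldSeries(aperm(array(M, c(d[4], d[1:3])), c(2, 3, 4, 1)),
               x@trSeconds, x@spacingMm, x@subjectId)
  })

gaussianKernel1d <- function(sigmaVox) {
  radius <- max(1L, ceiling(4 * sigmaVox))
  k <- exp(-((-radius):radius)^2 / (2 * sigmaVox^2))
  k / sum(k)
}

# Convolve along the first dimension of a 3D array with zero padding
# (mass-conserving for interior-supported inputs).
convolveAxis1 <- function(vol, kern) {
  d <- dim(vol)
  radius <- (length(kern) - 1L) / 2L
  M <- matrix(vol, d[1], d[2] * d[3])
  out <- matrix(0, d[1], d[2] * d[3])
  for (j in seq_along(kern)) {
    off <- j - 1L - radius
    src <- seq_len(d[1]) + off
    ok <- src >= 1L & src <= d[1]
    out[ok, ] <- out[ok, ] + kern[j] * M[src[ok], ]
  }
  array(out, d)
}

smoothVolume <- function(vol, sigmaVox) {
  for (axis in 1:3) {
    if (sigmaVox[axis] <= 0) next
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    v <- aperm(vol, perm)
    v <- convolveAxis1(v, gaussianKernel1d(sigmaVox[axis]))
    vol <- aperm(v, order(perm))
  }
  vol
}

#' Isotropic Gaussian spatial smoothing
#'
#' Convolves each volume with a separable Gaussian of the given full width at
#' half maximum (the FSL convention for "3 mm smoothing"). A FWHM of 0 is the
#' identity.
#'
#' @param series a [BoldSeries-class].
#' @param fwhmMm kernel full width at half maximum in millimetres (>= 0).
#' @return A smoothed [BoldSeries-class].
#' @export
spatialSmooth <- function(series, fwhmMm = 3.0) {
  if (fwhmMm < 0) stopWith("parameter", "fwhmMm must be nonnegative, got %g", fwhmMm)
  if (fwhmMm == 0) return(series)
  sigmaVox <- (fwhmMm / (2 * sqrt(2 * log(2)))) / series@spacingMm
  d <- dim(series@data)
  out <- series@data
  for (t in seq_len(d[4]))
    out[, , , t] <- smoothVolume(series@data[, , , t, drop = TRUE], sigmaVox)
  BoldSeries(out, series@trSeconds, series@spacingMm, series@subjectId)
}
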