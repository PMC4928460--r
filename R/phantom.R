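# Synthetic 4D BOLD phantom with known ground-truth sLFO structure.
#
# Each voxel mixes a subject-specific band-limited sLFO, delayed by a smooth
# voxelwise lag field, with a tissue-dependent mixing fraction (VA > GM > WM,
# CSF ~ 0), plus an aliased cardiac sinusoid confined to an inferior
# "arterial" zone, plus white noise.

#' Construct a PhantomSpec
#'
#' Defaults mirror the acquisition the pipeline targets (TR 0.72 s, 500
#' timepoints, 0.01-0.15 Hz band) and the assumed vascular-density ordering
#' of sLFO content: VA 0.9 > GM 0.5 > WM 0.15 > CSF 0.
#'
#' @param gridShape voxels per axis (3 integers).
#' @param nTimepoints number of timepoints.
#' @param trSeconds repetition time in seconds.
#' @param bandLowHz,bandHighHz sLFO band edges in Hz.
#' @param mixingFraction named numeric (wm, gm, csf, va, other) in [0, 1].
#' @param mixingJitter multiplicative voxelwise jitter half-width on mixing
#'   fractions (uniform in [1 - j, 1 + j], clipped to [0, 1]).
#' @param lagRangeS lag-field range in seconds, within [-6, 6].
#' @param cardiacHz cardiac frequency in Hz; sampled at the TR it aliases.
#' @param cardiacAmplitude named numeric (wm, gm, csf, va, other, arterial);
#'   largest in the inferior arterial zone by default.
#' @param noiseSd white-noise standard deviation.
#' @param spacingMm voxel spacing in millimetres.
#' @param rngSeed integer seed.
#' @param subjectId subject label.
#' @return A [PhantomSpec-class] object.
#' @export
phantomSpec <- function(gridShape = c(32L, 32L, 16L), nTimepoints = 500L,
                        trSeconds = 0.72, bandLowHz = 0.01, bandHighHz = 0.15,
                        mixingFraction = c(wm = 0.15, gm = 0.5, csf = 0,
                                           va = 0.9, other = 0),
                        mixingJitter = 0.15, lagRangeS = c(-4, 4),
                        cardiacHz = 1.1,
                        cardiacAmplitude = c(wm = 0, gm = 0, csf = 0, va = 0,
                                             other = 0, arterial = 0.6),
                        noiseSd = 2.0, spacingMm = c(2.5, 2.5, 2.5),
                        rngSeed = 1L, subjectId = "sub-01") {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      nTimepoints = as.integer(nTimepoints), trSeconds = trSeconds,
      bandLowHz = bandLowHz, bandHighHz = bandHighHz,
      mixingFraction = mixingFraction, mixingJitter = mixingJitter,
      lagRangeS = as.numeric(lagRangeS), cardiacHz = cardiacHz,
      cardiacAmplitude = cardiacAmplitude, noiseSd = noiseSd,
      spacingMm = as.numeric(spacingMm), rngSeed = as.integer(rngSeed),
      subjectId = subjectId)
}

# Band-limit a white-noise draw: keep only Fourier components inside the band,
# then standardize to zero mean and unit variance.
slfoCore <- function(white, trSeconds, bandLowHz, bandHighHz) {
  n <- length(white)
  freqs <- (seq_len(n) - 1) / (n * trSeconds)
  freqs <- pmin(freqs, 1 / trSeconds - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= bandLowHz & freqs <= bandHighHz
  if (!any(keep))
    stopWith("invalid_length",
             "no Fourier bin falls inside [%g, %g] Hz at n=%d, TR=%g s",
             bandLowHz, bandHighHz, n, trSeconds)
  spec <- fft(white)
  spec[!keep] <- 0
  x <- Re(fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x / sd(x)
}

#' Generate a band-limited sLFO timecourse
#'
#' Draws white noise and retains only its in-band Fourier components, giving a
#' zero-mean, unit-variance oscillation whose spectral energy outside the band
#' is negligible (< 1\% of total).
#'
#' @param nTimepoints number of timepoints (>= 100).
#' @param trSeconds sampling interval in seconds.
#' @param bandLowHz,bandHighHz band edges in Hz, 0 < low < high < Nyquist.
#' @param rngSeed integer seed; identical seeds give identical output.
#' @return Numeric vector of length \code{nTimepoints}.
#' @examples
#' s <- makeSlfoTimecourse(500, 0.72, 0.01, 0.15, rngSeed = 7)
#' c(mean(s), sd(s))
#' @export
makeSlfoTimecourse <- function(nTimepoints, trSeconds, bandLowHz = 0.01,
                               bandHighHz = 0.15, rngSeed = 1L) {
  checkBand(bandLowHz, bandHighHz, trSeconds)
  if (nTimepoints < 100L)
    stopWith("invalid_length", "need at least 100 timepoints, got %d", nTimepoints)
  withSeed(rngSeed,
           slfoCore(rnorm(nTimepoints), trSeconds, bandLowHz, bandHighHz))
}

# Deterministic concentric phantom geometry: WM core, GM shell, CSF rim inside
# an ellipsoidal brain; VA filaments plus a posterior-superior seed strip; an
# inferior arterial zone carved out of the tissue classes. Shell boundaries are
# radius quantiles so every class is populated even on very small grids.
phantomGeometry <- function(gridShape) {
  nx <- gridShape[1]; ny <- gridShape[2]; nz <- gridShape[3]
  ix <- rep(seq_len(nx), times = ny * nz)
  iy <- rep(rep(seq_len(ny), each = nx), times = nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  xn <- (ix - (nx + 1) / 2) / (nx / 2)
  yn <- (iy - (ny + 1) / 2) / (ny / 2)
  zn <- (iz - (nz + 1) / 2) / (nz / 2)
  r <- sqrt((xn / 0.95)^2 + (yn / 0.95)^2 + (zn / 0.95)^2)
  brain <- r <= 1
  if (sum(brain) < 20L)
    stopWith("geometry", "grid %s too small to populate all tissue masks",
             paste(gridShape, collapse = "x"))
  q <- quantile(r[brain], c(0.35, 0.78, 0.6, 0.9), names = FALSE)
  wm <- brain & r <= q[1]
  gm <- brain & r > q[1] & r <= q[2]
  csf <- brain & r > q[2]
  # seed strip: most posterior-superior voxels of the outer shell
  shell <- which(brain & r > q[3])
  nSss <- max(4L, round(0.005 * sum(brain)))
  sssIdx <- shell[order(yn[shell] + zn[shell], decreasing = TRUE)[seq_len(min(nSss, length(shell)))]]
  sss <- rep(FALSE, length(r)); sss[sssIdx] <- TRUE
  # vessel filaments: a sparse deterministic lattice of near-vertical lines
  fil <- brain & r <= q[4] & (ix %% 6L == 2L) & (iy %% 6L == 4L)
  va <- fil | sss
  # inferior arterial zone (around the brain base): cardiac-dominated, no sLFO
  arterial <- brain & zn <= quantile(zn[brain], 0.1) & sqrt(xn^2 + yn^2) < 0.6 & !va
  wm <- wm & !va & !arterial
  gm <- gm & !va & !arterial
  csf <- csf & !va & !arterial
  shp <- function(v) array(v, dim = gridShape)
  for (m in list(wm, gm, csf, va, sss))
    if (!any(m))
      stopWith("geometry", "a tissue mask is empty at grid %s",
               paste(gridShape, collapse = "x"))
  list(masks = TissueMasks(shp(wm), shp(gm), shp(csf), shp(va), shp(brain), shp(sss)),
       arterial = shp(arterial),
       coords = list(xn = shp(xn), yn = shp(yn), zn = shp(zn)))
}

#' Generate one synthetic BOLD phantom subject
#'
#' Builds concentric tissue masks, a smooth voxelwise lag field (realized as
#' whole-TR circular shifts of the planted sLFO, so the ground truth is exactly
#' representable on the analysis lag grid), tissue-dependent sLFO mixing, an
#' aliased cardiac sinusoid in the arterial zone, and white noise.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with elements \code{bold} ([BoldSeries-class]),
#'   \code{masks} ([TissueMasks-class]) and \code{truth}
#'   ([PhantomGroundTruth-class]).
#' @examples
#' ph <- generatePhantom(phantomSpec(gridShape = c(12, 12, 6), nTimepoints = 120))
#' ph$bold
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  geo <- phantomGeometry(spec@gridShape)
  masks <- geo$masks
  nVox <- prod(spec@gridShape)
  n <- spec@nTimepoints
  tr <- spec@trSeconds

  # exclusive voxel labels (VA precedence already applied by TissueMasks)
  lab <- rep("other", nVox)
  lab[maskArray(masks, "csf")] <- "csf"
  lab[maskArray(masks, "gm")] <- "gm"
  lab[maskArray(masks, "wm")] <- "wm"
  lab[maskArray(masks, "va")] <- "va"
  brain <- as.vector(brainMask(masks))

  withSeed(spec@rngSeed, {
    # smooth lag field: a random linear gradient mapped onto the lag range
    cf <- runif(3, -1, 1)
    jit <- if (spec@mixingJitter > 0)
      runif(nVox, 1 - spec@mixingJitter, 1 + spec@mixingJitter) else rep(1, nVox)
    slfo <- slfoCore(rnorm(n), tr, spec@bandLowHz, spec@bandHighHz)
    noise <- if (spec@noiseSd > 0)
      matrix(rnorm(n * nVox, sd = spec@noiseSd), n, nVox) else NULL
  })

  lin <- cf[1] * as.vector(geo$coords$xn) + cf[2] * as.vector(geo$coords$yn) +
    cf[3] * as.vector(geo$coords$zn)
  rng <- range(lin)
  u <- if (diff(rng) < 1e-12) rep(0.5, nVox) else (lin - rng[1]) / diff(rng)
  lo <- spec@lagRangeS[1]; hi <- spec@lagRangeS[2]
  if (lo <= 0 && hi >= 0) {
    # anchor the field at zero over the seed strip: measured lags are relative
    # to the seed regressor, so the ground truth is directly comparable
    uSss <- mean(u[as.vector(maskArray(masks, "sss"))])
    sc <- min(if (uSss < 1) hi / (1 - uSss) else Inf,
              if (uSss > 0) lo / (0 - uSss) else Inf)
    tau <- (u - uSss) * sc
  } else {
    tau <- lo + (hi - lo) * u
  }
  kShift <- as.integer(round(tau / tr))
  kShift[!brain] <- 0L
  trueLagS <- kShift * tr

  mix <- spec@mixingFraction[lab] * jit
  mix <- pmin(pmax(mix, 0), 1)
  mix[!brain] <- 0

  card <- spec@cardiacAmplitude[lab]
  card[as.vector(geo$arterial)] <- spec@cardiacAmplitude[["arterial"]]
  card[!brain] <- 0

  X <- if (is.null(noise)) matrix(0, n, nVox) else noise
  for (k in unique(kShift[brain & mix > 0])) {
    cols <- which(brain & mix > 0 & kShift == k)
    shifted <- slfo[((seq_len(n) - 1 - k) %% n) + 1]  # voxel delayed by k TRs
    X[, cols] <- X[, cols] + tcrossprod(shifted, mix[cols])
  }
  cc <- which(card > 0)
  if (length(cc)) {
    tt <- (seq_len(n) - 1) * tr
    X[, cc] <- X[, cc] + tcrossprod(cos(2 * pi * spec@cardiacHz * tt), card[cc])
  }

  data <- aperm(array(X, dim = c(n, spec@gridShape)), c(2, 3, 4, 1))
  truth <- new("PhantomGroundTruth",
               trueLagS = array(trueLagS, spec@gridShape),
               trueMixing = array(mix, spec@gridShape),
               slfo = slfo, rngSeed = spec@rngSeed)
  list(bold = BoldSeries(data, tr, spec@spacingMm, spec@subjectId),
       masks = masks, truth = truth)
}

#' Generate a cohort of phantom subjects
#'
#' Subjects share the (deterministic) geometry but have statistically
#' independent sLFO timecourses, lag fields and noise, through per-subject
#' seeds derived deterministically from \code{rngSeed}.
#'
#' @param nSubjects number of subjects (>= 2; the swap control needs pairs).
#' @param spec a [PhantomSpec-class] shared by all subjects.
#' @param rngSeed integer seed for the cohort.
#' @return List of per-subject lists as returned by [generatePhantom()].
#' @export
generateCohort <- function(nSubjects, spec = phantomSpec(), rngSeed = 1L) {
  if (nSubjects < 2L)
    stopWith("cohort_size", "a cohort needs at least 2 subjects, got %d", nSubjects)
  subSeeds <- withSeed(rngSeed, sample.int(.Machine$integer.max - 1L, nSubjects))
  lapply(seq_len(nSubjects), function(i) {
    si <- spec
    si@rngSeed <- subSeeds[i]
    si@subjectId <- sprintf("sub-%02d", i)
    generatePhantom(si)
  })
}
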