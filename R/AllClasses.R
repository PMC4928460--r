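#' @import methods
NULL

#' 4D BOLD-like voxel timeseries
#'
#' Container for a 4D (x, y, z, t) voxel timeseries grid together with its
#' sampling interval (the repetition time, TR) and voxel spacing. Every stage
#' of the pipeline consumes and produces this object.
#'
#' @slot data 4D numeric array, dimensions (x, y, z, t).
#' @slot trSeconds repetition time in seconds.
#' @slot spacingMm voxel spacing in millimetres, length 3.
#' @slot subjectId subject identifier carried through provenance.
#' @export
setClass("BoldSeries",
  representation(data = "array", trSeconds = "numeric",
                 spacingMm = "numeric", subjectId = "character"),
  validity = function(object) {
    if (length(dim(object@data)) != 4L) return("data must be a 4D array (x, y, z, t)")
    if (!all(is.finite(object@data))) return("data must be finite")
    if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
      return("trSeconds must be a single positive number")
    if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
      return("spacingMm must be three positive numbers")
    TRUE
  })

#' Construct a BoldSeries
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param trSeconds repetition time in seconds.
#' @param spacingMm voxel spacing in millimetres (length 3).
#' @param subjectId subject identifier.
#' @return A [BoldSeries-class] object.
#' @export
BoldSeries <- function(data, trSeconds, spacingMm = c(2.5, 2.5, 2.5),
                       subjectId = "subject") {
  new("BoldSeries", data = data, trSeconds = as.numeric(trSeconds),
      spacingMm = as.numeric(spacingMm), subjectId = subjectId)
}

#' Aligned binary tissue masks
#'
#' Binary masks for white matter (WM), gray matter (GM), cerebrospinal fluid
#' (CSF) and vasculature (VA) on one grid, plus a whole-brain mask and the
#' venous seed ROI (a superior-sagittal-sinus-like strip, a subset of VA).
#' The four tissue classes are pairwise disjoint: VA (vessel-mask derived)
#' takes precedence over the other labels, mirroring how a thresholded
#' angiogram is overlaid on an exclusive segmentation.
#'
#' @slot wm,gm,csf,va 3D logical arrays, one per tissue class.
#' @slot brain 3D logical array, union superset of all tissue classes.
#' @slot sss 3D logical array, seed ROI, subset of \code{va}.
#' @export
setClass("TissueMasks",
  representation(wm = "array", gm = "array", csf = "array",
                 va = "array", brain = "array", sss = "array"),
  validity = function(object) {
    flds <- list(wm = object@wm, gm = object@gm, csf = object@csf,
                 va = object@va, brain = object@brain, sss = object@sss)
    d <- dim(object@brain)
    for (nm in names(flds)) {
      if (!is.logical(flds[[nm]])) return(sprintf("mask '%s' must be logical", nm))
      if (!identical(dim(flds[[nm]]), d)) return("all masks must share one grid shape")
      if (!any(flds[[nm]])) return(sprintf("mask '%s' is empty", nm))
    }
    for (nm in c("wm", "gm", "csf", "va"))
      if (any(flds[[nm]] & !object@brain))
        return(sprintf("mask '%s' is not a subset of brain", nm))
    if (any(object@sss & !object@va)) return("sss must be a subset of va")
    pairs <- combn(c("wm", "gm", "csf", "va"), 2)
    for (p in seq_len(ncol(pairs)))
      if (any(flds[[pairs[1, p]]] & flds[[pairs[2, p]]]))
        return(sprintf("tissue masks '%s' and '%s' overlap",
                       pairs[1, p], pairs[2, p]))
    TRUE
  })

#' Construct TissueMasks, applying the VA-precedence exclusivity rule
#'
#' @param wm,gm,csf,va 3D logical tissue masks (may overlap VA on input).
#' @param brain 3D logical brain mask.
#' @param sss 3D logical seed ROI, subset of \code{va}.
#' @return A [TissueMasks-class] object with pairwise-disjoint tissue classes.
#' @export
TissueMasks <- function(wm, gm, csf, va, brain, sss) {
  # vessel mask wins; the remaining voxels keep their single segmentation label
  wm <- wm & !va; gm <- gm & !va; csf <- csf & !va
  new("TissueMasks", wm = wm, gm = gm, csf = csf, va = va,
      brain = brain, sss = sss)
}

#' Seed regressor timecourse
#'
#' The averaged timecourse over a vascular ROI, representing the systemic
#' low-frequency oscillation (sLFO) used as the lagged-correlation regressor.
#'
#' @slot values numeric timecourse.
#' @slot trSeconds sampling interval in seconds.
#' @slot sourceLabel text label of the source ROI (e.g. "SSS").
#' @slot subjectId subject the seed was extracted from.
#' @export
setClass("SeedTimecourse",
  representation(values = "numeric", trSeconds = "numeric",
                 sourceLabel = "character", subjectId = "character"),
  validity = function(object) {
    if (!all(is.finite(object@values))) return("values must be finite")
    if (object@trSeconds <= 0) return("trSeconds must be positive")
    TRUE
  })

#' Voxelwise maximum lagged-correlation map
#'
#' Per-voxel maximum Pearson correlation (\code{maxcc}) with a seed regressor
#' over a lag window, the optimal lag, and the validity mask
#' (maxcc strictly above the threshold, lag inside the window).
#'
#' @slot maxcc 3D numeric array in [-1, 1]; NA outside the brain mask.
#' @slot lagS 3D numeric array of optimal lags in seconds; NA outside brain.
#' @slot valid 3D logical array of valid voxels.
#' @slot threshold minimum correlation applied (default 0.3).
#' @slot lagLimitS lag window half-width in seconds (default 6).
#' @slot trSeconds repetition time of the underlying series.
#' @slot subjectId,seedLabel provenance labels.
#' @export
setClass("LagCorrelationMap",
  representation(maxcc = "array", lagS = "array", valid = "array",
                 threshold = "numeric", lagLimitS = "numeric",
                 trSeconds = "numeric", subjectId = "character",
                 seedLabel = "character"),
  validity = function(object) {
    d <- dim(object@maxcc)
    if (!identical(dim(object@lagS), d) || !identical(dim(object@valid), d))
      return("maxcc, lagS and valid must share one grid shape")
    v <- object@valid
    cc <- object@maxcc[v]; lg <- object@lagS[v]
    if (any(!is.finite(cc)) || any(!is.finite(lg)))
      return("maxcc and lagS must be finite on valid voxels")
    if (any(cc <= object@threshold))
      return("valid voxels must have maxcc strictly above the threshold")
    if (any(abs(lg) > object@lagLimitS + 1e-9))
      return("valid voxels must have |lag| within the lag window")
    if (any(abs(lg / object@trSeconds - round(lg / object@trSeconds)) > 1e-6))
      return("lags must be integer multiples of the TR")
    ccAll <- object@maxcc[is.finite(object@maxcc)]
    if (length(ccAll) && any(abs(ccAll) > 1 + 1e-12))
      return("maxcc must lie within [-1, 1]")
    TRUE
  })

#' ALFF map
#'
#' Per-voxel amplitude of low-frequency fluctuation: the one-sided amplitude
#' spectrum summed over the low-frequency band.
#'
#' @slot alff 3D nonnegative numeric array; NA outside the brain mask.
#' @slot band numeric length 2, (low, high) in Hz.
#' @slot subjectId provenance label.
#' @export
setClass("AlffMap",
  representation(alff = "array", band = "numeric", subjectId = "character"),
  validity = function(object) {
    a <- object@alff[is.finite(object@alff)]
    if (length(a) && any(a < -1e-12)) return("alff must be nonnegative")
    if (length(object@band) != 2L || object@band[1] >= object@band[2])
      return("band must be (low, high) with low < high")
    TRUE
  })

#' Equal-count bin assignment
#'
#' Assignment of valid voxels to equal-count bins by ascending map value.
#'
#' @slot binIndex 3D integer array, 1..nBins on valid voxels, 0 elsewhere.
#' @slot nBins number of bins.
#' @slot binEdges map values at the upper boundary of bins 1..nBins-1.
#' @slot nValid number of valid voxels binned.
#' @export
setClass("BinAssignment",
  representation(binIndex = "array", nBins = "integer",
                 binEdges = "numeric", nValid = "integer"),
  validity = function(object) {
    counts <- tabulate(object@binIndex[object@binIndex > 0L], object@nBins)
    if (sum(counts) != object@nValid) return("bin counts must sum to nValid")
    if (diff(range(counts)) > 1L) return("bin counts must differ by at most 1")
    TRUE
  })

#' Tissue distribution table
#'
#' Per-bin tissue composition of the valid voxels: each row is one bin of the
#' ascending-map-value ranking, each column the fraction of that bin's voxels
#' carrying one exclusive tissue label (GM, WM, CSF, VA, other).
#'
#' @slot fractions nBins x 5 numeric matrix, rows summing to 1.
#' @slot subjectId provenance label.
#' @slot sourceMap which map was ranked: "maxcc", "alff" or "maxcc_swap".
#' @export
setClass("DistributionTable",
  representation(fractions = "matrix", subjectId = "character",
                 sourceMap = "character"),
  validity = function(object) {
    f <- object@fractions
    if (!identical(colnames(f), c("GM", "WM", "CSF", "VA", "other")))
      return("columns must be GM, WM, CSF, VA, other")
    if (any(f < -1e-12) || any(f > 1 + 1e-12)) return("fractions must lie in [0, 1]")
    if (any(abs(rowSums(f) - 1) > 1e-12)) return("each row must sum to 1")
    TRUE
  })

#' Group-averaged tissue distribution
#'
#' Entrywise mean and sample standard deviation of per-subject
#' [DistributionTable-class] fractions.
#'
#' @slot meanFractions,sdFractions nBins x 5 numeric matrices.
#' @slot nSubjects number of tables averaged.
#' @export
setClass("GroupDistribution",
  representation(meanFractions = "matrix", sdFractions = "matrix",
                 nSubjects = "integer"),
  validity = function(object) {
    if (!identical(dim(object@meanFractions), dim(object@sdFractions)))
      return("mean and sd matrices must share one shape")
    if (any(object@sdFractions < 0)) return("sd must be nonnegative")
    if (any(abs(rowSums(object@meanFractions) - 1) > 1e-12))
      return("mean rows must sum to 1")
    TRUE
  })

#' Specification of a synthetic BOLD phantom
#'
#' Parameters of the synthetic 4D phantom: grid, sampling, the sLFO band,
#' tissue-dependent sLFO mixing fractions (ordered VA > GM > WM, CSF ~ 0),
#' the smooth voxelwise lag field, an aliased cardiac sinusoid confined to an
#' inferior arterial zone, and white measurement noise.
#'
#' @slot gridShape 3 positive integers, voxels per axis.
#' @slot nTimepoints number of timepoints.
#' @slot trSeconds repetition time in seconds.
#' @slot bandLowHz,bandHighHz sLFO band edges in Hz.
#' @slot mixingFraction named numeric (wm, gm, csf, va, other) in [0, 1].
#' @slot mixingJitter multiplicative voxelwise jitter half-width on mixing.
#' @slot lagRangeS lag-field range in seconds, within [-6, 6].
#' @slot cardiacHz cardiac frequency in Hz (aliased at the TR).
#' @slot cardiacAmplitude named numeric (wm, gm, csf, va, other, arterial).
#' @slot noiseSd white-noise standard deviation.
#' @slot spacingMm voxel spacing in millimetres.
#' @slot rngSeed integer seed.
#' @slot subjectId subject label.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", nTimepoints = "integer",
                 trSeconds = "numeric", bandLowHz = "numeric",
                 bandHighHz = "numeric", mixingFraction = "numeric",
                 mixingJitter = "numeric", lagRangeS = "numeric",
                 cardiacHz = "numeric", cardiacAmplitude = "numeric",
                 noiseSd = "numeric", spacingMm = "numeric",
                 rngSeed = "integer", subjectId = "character"),
  validity = function(object) {
    if (length(object@gridShape) != 3L || any(object@gridShape < 4L))
      return("gridShape must be 3 integers, each at least 4")
    if (object@nTimepoints < 2L) return("nTimepoints must be positive")
    if (object@trSeconds <= 0) return("trSeconds must be positive")
    if (!(object@bandLowHz > 0 && object@bandLowHz < object@bandHighHz &&
          object@bandHighHz < nyquistHz(object@trSeconds)))
      return("band must satisfy 0 < low < high < Nyquist")
    lbl <- c("wm", "gm", "csf", "va", "other")
    if (!all(lbl %in% names(object@mixingFraction)))
      return("mixingFraction must name wm, gm, csf, va, other")
    if (any(object@mixingFraction < 0) || any(object@mixingFraction > 1))
      return("mixing fractions must lie in [0, 1]")
    if (object@mixingJitter < 0 || object@mixingJitter >= 1)
      return("mixingJitter must lie in [0, 1)")
    if (length(object@lagRangeS) != 2L || object@lagRangeS[1] > object@lagRangeS[2] ||
        any(abs(object@lagRangeS) > 6))
      return("lagRangeS must be an ordered pair within [-6, 6] seconds")
    if (!all(c(lbl, "arterial") %in% names(object@cardiacAmplitude)))
      return("cardiacAmplitude must name wm, gm, csf, va, other, arterial")
    if (any(object@cardiacAmplitude < 0)) return("cardiac amplitudes must be nonnegative")
    if (object@noiseSd < 0) return("noiseSd must be nonnegative")
    TRUE
  })

#' Ground truth planted in a phantom
#'
#' @slot trueLagS 3D numeric array of planted lags (seconds), 0 outside brain.
#' @slot trueMixing 3D numeric array of planted sLFO mixing fractions.
#' @slot slfo the planted unit-variance sLFO timecourse.
#' @slot rngSeed the seed the phantom was generated from.
#' @export
setClass("PhantomGroundTruth",
  representation(trueLagS = "array", trueMixing = "array",
                 slfo = "numeric", rngSeed = "integer"),
  validity = function(object) {
    if (any(abs(object@trueLagS) > 6 + 1e-9)) return("|trueLagS| must be <= 6 s")
    if (any(object@trueMixing < 0) || any(object@trueMixing > 1))
      return("trueMixing must lie in [0, 1]")
    TRUE
  })

#' Result of the swapped-seed null control
#'
#' Every subject's maxcc map recomputed with every other subject's seed
#' regressor, with the resulting (null) distribution tables and slope tests.
#'
#' @slot maps list of [LagCorrelationMap-class], one per ordered subject pair.
#' @slot tables list of [DistributionTable-class] for maps with enough valid voxels.
#' @slot group the averaged [GroupDistribution-class] (or NULL if < 2 tables).
#' @slot slopeTests data.frame of per-tissue slope-vs-zero tests over the maps.
#' @slot slopes data.frame of per-map, per-tissue fitted slopes.
#' @slot pairs data.frame with columns dataSubject, seedSubject, nValid, used.
#' @slot nInsufficient number of maps with fewer valid voxels than bins.
#' @export
setClass("SwapResult",
  representation(maps = "list", tables = "list", group = "ANY",
                 slopeTests = "data.frame", slopes = "data.frame",
                 pairs = "data.frame", nInsufficient = "integer"))

#' Analysis configuration
#'
#' All fixed constants of the pipeline in one object: the 0.01-0.15 Hz band,
#' order-3 zero-phase Butterworth filter, 3 mm FWHM smoothing, the 0.3 maxcc
#' threshold, the +/-6 s lag window and the 10 equal-count bins.
#'
#' @slot bandLowHz,bandHighHz temporal band edges in Hz.
#' @slot filterOrder Butterworth order.
#' @slot fwhmMm spatial smoothing FWHM in millimetres.
#' @slot maxccThreshold minimum correlation for a valid voxel.
#' @slot lagLimitS lag window half-width in seconds.
#' @slot nBins number of equal-count bins.
#' @slot alffValidMode voxels ranked for the ALFF distribution:
#'   "brain" (all brain voxels) or "maxcc_valid" (reuse the maxcc validity mask).
#' @slot swapPooling swap-control slope units: "per_map" or "per_subject".
#' @slot rngSeed integer seed for any stochastic stage.
#' @slot inputDir,outputDir optional paths.
#' @export
setClass("AnalysisConfig",
  representation(bandLowHz = "numeric", bandHighHz = "numeric",
                 filterOrder = "integer", fwhmMm = "numeric",
                 maxccThreshold = "numeric", lagLimitS = "numeric",
                 nBins = "integer", alffValidMode = "character",
                 swapPooling = "character", rngSeed = "integer",
                 inputDir = "character", outputDir = "character"),
  validity = function(object) {
    if (object@bandLowHz <= 0 || object@bandLowHz >= object@bandHighHz)
      return("band must satisfy 0 < low < high")
    if (object@filterOrder < 1L) return("filterOrder must be >= 1")
    if (object@fwhmMm < 0) return("fwhmMm must be nonnegative")
    if (object@lagLimitS <= 0) return("lagLimitS must be positive")
    if (object@nBins < 2L) return("nBins must be >= 2")
    if (!object@alffValidMode %in% c("brain", "maxcc_valid"))
      return("alffValidMode must be 'brain' or 'maxcc_valid'")
    if (!object@swapPooling %in% c("per_map", "per_subject"))
      return("swapPooling must be 'per_map' or 'per_subject'")
    TRUE
  })
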