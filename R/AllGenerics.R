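# Accessor generics: user code should reach slots through these, never via @.

#' @rdname accessors
#' @param x an object of one of the package's classes.
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("boldData", function(x) standardGeneric("boldData"))
#' @rdname accessors
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))
#' @rdname accessors
#' @param label one of "wm", "gm", "csf", "va", "brain", "sss".
#' @export
setGeneric("maskArray", function(x, label) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))
#' @rdname accessors
#' @export
setGeneric("seedValues", function(x) standardGeneric("seedValues"))
#' @rdname accessors
#' @export
setGeneric("maxccArray", function(x) standardGeneric("maxccArray"))
#' @rdname accessors
#' @export
setGeneric("lagArray", function(x) standardGeneric("lagArray"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("nValid", function(x) standardGeneric("nValid"))
#' @rdname accessors
#' @export
setGeneric("alffArray", function(x) standardGeneric("alffArray"))
#' @rdname accessors
#' @export
setGeneric("binIndexArray", function(x) standardGeneric("binIndexArray"))
#' @rdname accessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))
#' @rdname accessors
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))
#' @rdname accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))
#' @rdname accessors
#' @export
setGeneric("meanFractions", function(x) standardGeneric("meanFractions"))
#' @rdname accessors
#' @export
setGeneric("sdFractions", function(x) standardGeneric("sdFractions"))
#' @rdname accessors
#' @export
setGeneric("trueLag", function(x) standardGeneric("trueLag"))
#' @rdname accessors
#' @export
setGeneric("trueMixing", function(x) standardGeneric("trueMixing"))
#' @rdname accessors
#' @export
setGeneric("slfoTimecourse", function(x) standardGeneric("slfoTimecourse"))
#' @rdname accessors
#' @export
setGeneric("swapMaps", function(x) standardGeneric("swapMaps"))
#' @rdname accessors
#' @export
setGeneric("swapTables", function(x) standardGeneric("swapTables"))
#' @rdname accessors
#' @export
setGeneric("swapPairs", function(x) standardGeneric("swapPairs"))
#' @rdname accessors
#' @export
setGeneric("swapSlopes", function(x) standardGeneric("swapSlopes"))
#' @rdname accessors
#' @export
setGeneric("slopeTests", function(x) standardGeneric("slopeTests"))

#' Accessors for slfomap classes
#'
#' @name accessors
#' @return The slot content named by the accessor.
NULL

#' @rdname accessors
setMethod("trSeconds", "BoldSeries", function(x) x@trSeconds)
#' @rdname accessors
setMethod("trSeconds", "SeedTimecourse", function(x) x@trSeconds)
#' @rdname accessors
setMethod("trSeconds", "LagCorrelationMap", function(x) x@trSeconds)
#' @rdname accessors
setMethod("subjectId", "BoldSeries", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "SeedTimecourse", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "LagCorrelationMap", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "AlffMap", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "DistributionTable", function(x) x@subjectId)
#' @rdname accessors
setMethod("boldData", "BoldSeries", function(x) x@data)
#' @rdname accessors
setMethod("spacingMm", "BoldSeries", function(x) x@spacingMm)
#' @rdname accessors
setMethod("maskArray", "TissueMasks", function(x, label) {
  label <- match.arg(label, c("wm", "gm", "csf", "va", "brain", "sss"))
  slot(x, label)
})
#' @rdname accessors
setMethod("brainMask", "TissueMasks", function(x) x@brain)
#' @rdname accessors
setMethod("seedValues", "SeedTimecourse", function(x) x@values)
#' @rdname accessors
setMethod("maxccArray", "LagCorrelationMap", function(x) x@maxcc)
#' @rdname accessors
setMethod("lagArray", "LagCorrelationMap", function(x) x@lagS)
#' @rdname accessors
setMethod("validMask", "LagCorrelationMap", function(x) x@valid)
#' @rdname accessors
setMethod("nValid", "LagCorrelationMap", function(x) sum(x@valid))
#' @rdname accessors
setMethod("nValid", "BinAssignment", function(x) x@nValid)
#' @rdname accessors
setMethod("alffArray", "AlffMap", function(x) x@alff)
#' @rdname accessors
setMethod("binIndexArray", "BinAssignment", function(x) x@binIndex)
#' @rdname accessors
setMethod("nBins", "BinAssignment", function(x) x@nBins)
#' @rdname accessors
setMethod("binEdges", "BinAssignment", function(x) x@binEdges)
#' @rdname accessors
setMethod("fractions", "DistributionTable", function(x) x@fractions)
#' @rdname accessors
setMethod("meanFractions", "GroupDistribution", function(x) x@meanFractions)
#' @rdname accessors
setMethod("sdFractions", "GroupDistribution", function(x) x@sdFractions)
#' @rdname accessors
setMethod("trueLag", "PhantomGroundTruth", function(x) x@trueLagS)
#' @rdname accessors
setMethod("trueMixing", "PhantomGroundTruth", function(x) x@trueMixing)
#' @rdname accessors
setMethod("slfoTimecourse", "PhantomGroundTruth", function(x) x@slfo)
#' @rdname accessors
setMethod("swapMaps", "SwapResult", function(x) x@maps)
#' @rdname accessors
setMethod("swapTables", "SwapResult", function(x) x@tables)
#' @rdname accessors
setMethod("swapPairs", "SwapResult", function(x) x@pairs)
#' @rdname accessors
setMethod("swapSlopes", "SwapResult", function(x) x@slopes)
#' @rdname accessors
setMethod("slopeTests", "SwapResult", function(x) x@slopeTests)

setMethod("show", "BoldSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("BoldSeries '%s': %dx%dx%d voxels x %d timepoints, TR %.3g s\n",
              object@subjectId, d[1], d[2], d[3], d[4], object@trSeconds))
})

setMethod("show", "TissueMasks", function(object) {
  cat(sprintf(
    "TissueMasks %s: brain %d | WM %d GM %d CSF %d VA %d | seed ROI %d voxels\n",
    paste(dim(object@brain), collapse = "x"), sum(object@brain), sum(object@wm),
    sum(object@gm), sum(object@csf), sum(object@va), sum(object@sss)))
})

setMethod("show", "SeedTimecourse", function(object) {
  cat(sprintf("SeedTimecourse '%s' (%s): %d timepoints, TR %.3g s\n",
              object@sourceLabel, object@subjectId, length(object@values),
              object@trSeconds))
})

setMethod("show", "LagCorrelationMap", function(object) {
  cat(sprintf(
    "LagCorrelationMap '%s' (seed %s): %s grid, threshold %.2g, lag window +/-%g s\n  %d valid voxels\n",
    object@subjectId, object@seedLabel, paste(dim(object@maxcc), collapse = "x"),
    object@threshold, object@lagLimitS, sum(object@valid)))
})

setMethod("show", "AlffMap", function(object) {
  cat(sprintf("AlffMap '%s': %s grid, band %.3g-%.3g Hz\n", object@subjectId,
              paste(dim(object@alff), collapse = "x"), object@band[1], object@band[2]))
})

setMethod("show", "BinAssignment", function(object) {
  cat(sprintf("BinAssignment: %d valid voxels in %d equal-count bins\n",
              object@nValid, object@nBins))
})

setMethod("show", "DistributionTable", function(object) {
  cat(sprintf("DistributionTable '%s' (%s), %d bins:\n", object@subjectId,
              object@sourceMap, nrow(object@fractions)))
  print(round(object@fractions, 3))
})

setMethod("show", "GroupDistribution", function(object) {
  cat(sprintf("GroupDistribution over %d subjects, %d bins (mean fractions):\n",
              object@nSubjects, nrow(object@meanFractions)))
  print(round(object@meanFractions, 3))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec '%s': %s grid, %d timepoints, TR %.3g s, band %.3g-%.3g Hz\n  mixing %s | lag range [%g, %g] s | noise sd %.3g | seed %d\n",
    object@subjectId, paste(object@gridShape, collapse = "x"),
    object@nTimepoints, object@trSeconds, object@bandLowHz, object@bandHighHz,
    paste(sprintf("%s=%.2g", names(object@mixingFraction), object@mixingFraction),
          collapse = " "),
    object@lagRangeS[1], object@lagRangeS[2], object@noiseSd, object@rngSeed))
})

setMethod("show", "SwapResult", function(object) {
  cat(sprintf(
    "SwapResult: %d swapped maps (%d with enough valid voxels for binning)\n",
    length(object@maps), length(object@tables)))
  if (nrow(object@slopeTests)) print(object@slopeTests)
})

setMethod("show", "AnalysisConfig", function(object) {
  cat(sprintf(
    "AnalysisConfig: band %.3g-%.3g Hz (order %d), FWHM %g mm, threshold %.2g,\n  lag window +/-%g s, %d bins, ALFF ranking on '%s', swap pooling '%s', seed %d\n",
    object@bandLowHz, object@bandHighHz, object@filterOrder, object@fwhmMm,
    object@maxccThreshold, object@lagLimitS, object@nBins, object@alffValidMode,
    object@swapPooling, object@rngSeed))
})
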