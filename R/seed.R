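# Seed regressor: the averaged timecourse over a vascular ROI (typically a
# superior-sagittal-sinus strip), representing the systemic low-frequency
# oscillation. The series is expected to be band-pass filtered already; the
# extraction itself is an unweighted mean.

#' Extract the seed regressor from a vascular ROI
#'
#' @param series a [BoldSeries-class], already band-pass filtered.
#' @param roiMask 3D logical array on the same grid as \code{series};
#'   typically the \code{sss} mask of [TissueMasks-class].
#' @param sourceLabel text label recorded with the seed (default "SSS").
#' @return A [SeedTimecourse-class]: the unweighted mean over ROI voxels at
#'   each timepoint.
#' @examples
#' ph <- generatePhantom(phantomSpec(gridShape = c(12, 12, 6), nTimepoints = 120))
#' extractSeed(ph$bold, maskArray(ph$masks, "sss"))
#' @export
extractSeed <- function(series, roiMask, sourceLabel = "SSS") {
  checkSameGrid(series@data, roiMask, "series and ROI mask")
  idx <- which(roiMask)
  if (!length(idx)) stopWith("empty_roi", "the ROI mask contains no voxels")
  M <- asVoxelMatrix(series@data)
  new("SeedTimecourse",
      values = colMeans(M[idx, , drop = FALSE]),
      trSeconds = series@trSeconds, sourceLabel = sourceLabel,
      subjectId = series@subjectId)
}
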