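# NIfTI-1 and plain-text I/O. 4D series carry their TR in the header's fourth
# pixdim; masks are written as 0/1 integer volumes; seeds as one value per
# line with a small key-value sidecar.

writeNiftiArray <- function(arr, path, spacingMm, trSeconds = NULL) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- if (is.null(trSeconds)) spacingMm
                         else c(spacingMm, trSeconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a 4D BOLD series as NIfTI-1
#'
#' The TR is stored in (and recovered from) the fourth pixdim of the header.
#'
#' @param series a [BoldSeries-class].
#' @param path file path (.nii or .nii.gz).
#' @param subjectId subject label attached on read.
#' @return \code{writeBold} returns the path invisibly; \code{readBold}
#'   returns a [BoldSeries-class].
#' @export
writeBold <- function(series, path) {
  writeNiftiArray(series@data, path, series@spacingMm, series@trSeconds)
}

#' @rdname writeBold
#' @export
readBold <- function(path, subjectId = "subject") {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (length(dim(img)) != 4L)
    stopWith("shape", "'%s' is not a 4D NIfTI volume", path)
  if (length(pd) < 4L || pd[4] <= 0)
    stopWith("sampling", "'%s' carries no repetition time in pixdim[4]", path)
  BoldSeries(array(as.numeric(img), dim(img)), trSeconds = pd[4],
             spacingMm = pd[1:3], subjectId = subjectId)
}

#' Read / write a 3D binary mask as NIfTI-1
#'
#' @param mask 3D logical array.
#' @param path file path.
#' @param spacingMm voxel spacing in millimetres.
#' @return \code{writeMask} returns the path invisibly; \code{readMask}
#'   returns a 3D logical array.
#' @export
writeMask <- function(mask, path, spacingMm = c(2.5, 2.5, 2.5)) {
  writeNiftiArray(array(as.integer(mask), dim(mask)), path, spacingMm)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) != 0, dim(img))
}

#' Write / read all tissue masks of a subject
#'
#' One NIfTI file per mask (wm, gm, csf, va, brain, sss) inside \code{dir}.
#'
#' @param masks a [TissueMasks-class].
#' @param dir directory (created if needed).
#' @param spacingMm voxel spacing in millimetres.
#' @return \code{writeTissueMasks} returns \code{dir} invisibly;
#'   \code{readTissueMasks} returns a [TissueMasks-class].
#' @export
writeTissueMasks <- function(masks, dir, spacingMm = c(2.5, 2.5, 2.5)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("wm", "gm", "csf", "va", "brain", "sss"))
    writeMask(maskArray(masks, nm), file.path(dir, paste0(nm, ".nii.gz")), spacingMm)
  invisible(dir)
}

#' @rdname writeTissueMasks
#' @export
readTissueMasks <- function(dir) {
  rd <- function(nm) readMask(file.path(dir, paste0(nm, ".nii.gz")))
  TissueMasks(rd("wm"), rd("gm"), rd("csf"), rd("va"), rd("brain"), rd("sss"))
}

#' Write / read a seed timecourse as plain text
#'
#' One value per line, plus a key-value sidecar (\code{<path>.meta}) recording
#' the TR, ROI label and subject.
#'
#' @param seed a [SeedTimecourse-class].
#' @param path text file path.
#' @return \code{writeSeed} returns the path invisibly; \code{readSeed}
#'   returns a [SeedTimecourse-class].
#' @export
writeSeed <- function(seed, path) {
  writeLines(format(seed@values, digits = 17), path)
  writeLines(c(sprintf("tr_seconds: %.17g", seed@trSeconds),
               sprintf("source_label: %s", seed@sourceLabel),
               sprintf("subject_id: %s", seed@subjectId),
               sprintf("n_timepoints: %d", length(seed@values))),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname writeSeed
#' @export
readSeed <- function(path) {
  vals <- as.numeric(readLines(path))
  meta <- yaml::read_yaml(paste0(path, ".meta"))
  new("SeedTimecourse", values = vals, trSeconds = as.numeric(meta$tr_seconds),
      sourceLabel = as.character(meta$source_label),
      subjectId = as.character(meta$subject_id))
}

#' Write a lag-correlation map as NIfTI volumes plus a text sidecar
#'
#' Writes \code{<prefix>_maxcc.nii.gz}, \code{<prefix>_lag.nii.gz},
#' \code{<prefix>_valid.nii.gz} and \code{<prefix>_info.txt} (threshold, lag
#' window, valid-voxel count).
#'
#' @param map a [LagCorrelationMap-class].
#' @param prefix path prefix.
#' @param spacingMm voxel spacing in millimetres.
#' @return The prefix, invisibly.
#' @export
writeLagMap <- function(map, prefix, spacingMm = c(2.5, 2.5, 2.5)) {
  mc <- map@maxcc; mc[is.na(mc)] <- 0
  lg <- map@lagS; lg[is.na(lg)] <- 0
  writeNiftiArray(mc, paste0(prefix, "_maxcc.nii.gz"), spacingMm)
  writeNiftiArray(lg, paste0(prefix, "_lag.nii.gz"), spacingMm)
  writeMask(map@valid, paste0(prefix, "_valid.nii.gz"), spacingMm)
  writeLines(c(sprintf("threshold: %g", map@threshold),
               sprintf("lag_limit_s: %g", map@lagLimitS),
               sprintf("n_valid: %d", sum(map@valid)),
               sprintf("seed_label: %s", map@seedLabel),
               sprintf("subject_id: %s", map@subjectId)),
             paste0(prefix, "_info.txt"))
  invisible(prefix)
}

#' Write a distribution table as TSV
#'
#' @param table a [DistributionTable-class] or [GroupDistribution-class].
#' @param path TSV path.
#' @return The path, invisibly.
#' @export
writeDistributionTable <- function(table, path) {
  f <- if (is(table, "GroupDistribution")) table@meanFractions else table@fractions
  df <- data.frame(bin = seq_len(nrow(f)), f, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
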