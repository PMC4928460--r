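# Pipeline orchestration: per-subject and cohort analysis from one
# configuration object, with optional on-disk outputs and a run manifest.

#' Construct an AnalysisConfig
#'
#' Defaults are the pipeline's fixed constants: 0.01-0.15 Hz order-3
#' zero-phase Butterworth band-pass, 3 mm FWHM smoothing, maxcc threshold 0.3,
#' +/-6 s lag window, 10 equal-count bins.
#'
#' @param bandLowHz,bandHighHz temporal band edges in Hz.
#' @param filterOrder Butterworth order.
#' @param fwhmMm spatial smoothing FWHM in millimetres.
#' @param maxccThreshold minimum correlation for a valid voxel (strict).
#' @param lagLimitS lag window half-width in seconds.
#' @param nBins number of equal-count bins.
#' @param alffValidMode voxels ranked for the ALFF distribution: "brain" or
#'   "maxcc_valid".
#' @param swapPooling swap-control slope units: "per_map" or "per_subject".
#' @param rngSeed integer seed for stochastic stages.
#' @param inputDir,outputDir optional paths recorded in the manifest.
#' @return An [AnalysisConfig-class].
#' @export
analysisConfig <- function(bandLowHz = 0.01, bandHighHz = 0.15,
                           filterOrder = 3L, fwhmMm = 3.0,
                           maxccThreshold = 0.3, lagLimitS = 6.0,
                           nBins = 10L, alffValidMode = "brain",
                           swapPooling = "per_map", rngSeed = 1L,
                           inputDir = "", outputDir = "") {
  new("AnalysisConfig", bandLowHz = bandLowHz, bandHighHz = bandHighHz,
      filterOrder = as.integer(filterOrder), fwhmMm = fwhmMm,
      maxccThreshold = maxccThreshold, lagLimitS = lagLimitS,
      nBins = as.integer(nBins), alffValidMode = alffValidMode,
      swapPooling = swapPooling, rngSeed = as.integer(rngSeed),
      inputDir = inputDir, outputDir = outputDir)
}

configAsList <- function(config) {
  list(band_low_hz = config@bandLowHz, band_high_hz = config@bandHighHz,
       filter_order = config@filterOrder, fwhm_mm = config@fwhmMm,
       maxcc_threshold = config@maxccThreshold, lag_limit_s = config@lagLimitS,
       n_bins = config@nBins, alff_valid_mode = config@alffValidMode,
       swap_pooling = config@swapPooling, rng_seed = config@rngSeed,
       input_dir = config@inputDir, output_dir = config@outputDir)
}

#' Write / read an AnalysisConfig as YAML
#'
#' The file form round-trips losslessly.
#'
#' @param config an [AnalysisConfig-class].
#' @param path YAML file path.
#' @return \code{writeAnalysisConfig} returns the path invisibly;
#'   \code{readAnalysisConfig} returns an [AnalysisConfig-class].
#' @export
writeAnalysisConfig <- function(config, path) {
  yaml::write_yaml(configAsList(config), path, precision = 17)
  invisible(path)
}

#' @rdname writeAnalysisConfig
#' @export
readAnalysisConfig <- function(path) {
  v <- yaml::read_yaml(path)
  analysisConfig(bandLowHz = v$band_low_hz, bandHighHz = v$band_high_hz,
                 filterOrder = v$filter_order, fwhmMm = v$fwhm_mm,
                 maxccThreshold = v$maxcc_threshold, lagLimitS = v$lag_limit_s,
                 nBins = v$n_bins, alffValidMode = v$alff_valid_mode,
                 swapPooling = v$swap_pooling, rngSeed = v$rng_seed,
                 inputDir = v$input_dir, outputDir = v$output_dir)
}

# Manifest: config snapshot, package version, per-file md5 checksums,
# valid-voxel counts and timestamps, written as YAML next to the outputs.
writeManifest <- function(dir, config, stageInfo) {
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.yaml"]
  sums <- tools::md5sum(files)
  manifest <- list(software = sprintf("slfomap %s", as.character(packageVersion("slfomap"))),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = configAsList(config),
                   stages = stageInfo,
                   checksums = as.list(stats::setNames(unname(sums),
                                                       basename(names(sums)))))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Run the full per-subject analysis
#'
#' Smooth (spatial) -> band-pass (temporal) -> extract the venous seed ->
#' maxcc map -> ALFF map -> rank/bin both maps -> tissue fractions -> slopes.
#'
#' @param bold a raw [BoldSeries-class].
#' @param masks a [TissueMasks-class] on the same grid.
#' @param config an [AnalysisConfig-class].
#' @param outDir optional output directory; when given, all maps, tables and a
#'   run manifest are written there.
#' @return List with elements \code{filtered} (the preprocessed series),
#'   \code{seed}, \code{maxccMap}, \code{alffMap}, \code{maxccTable},
#'   \code{alffTable}, \code{slopes} (data.frame over tissues and sources).
#' @export
runSubject <- function(bold, masks, config = analysisConfig(), outDir = NULL) {
  sm <- spatialSmooth(bold, config@fwhmMm)
  filt <- bandpassFilter(sm, config@bandLowHz, config@bandHighHz,
                         config@filterOrder)
  seed <- extractSeed(filt, maskArray(masks, "sss"))
  maxccMap <- computeMaxccMap(filt, seed, brainMask(masks),
                              threshold = config@maxccThreshold,
                              lagLimitS = config@lagLimitS)
  alffMap <- computeAlff(filt, brainMask(masks),
                         config@bandLowHz, config@bandHighHz)

  maxccBins <- rankAndBin(maxccArray(maxccMap), validMask(maxccMap), config@nBins)
  maxccTable <- binTissueFractions(maxccBins, masks,
                                   subjectId = subjectId(bold), sourceMap = "maxcc")
  alffValid <- if (config@alffValidMode == "brain") brainMask(masks)
               else validMask(maxccMap)
  alffBins <- rankAndBin(alffArray(alffMap), alffValid, config@nBins)
  alffTable <- binTissueFractions(alffBins, masks,
                                  subjectId = subjectId(bold), sourceMap = "alff")

  slopes <- do.call(rbind, lapply(c("GM", "WM", "CSF", "VA"), function(tis) {
    rbind(cbind(fitDistributionSlope(maxccTable, tis), sourceMap = "maxcc"),
          cbind(fitDistributionSlope(alffTable, tis), sourceMap = "alff"))
  }))

  res <- list(filtered = filt, seed = seed, maxccMap = maxccMap,
              alffMap = alffMap, maxccBins = maxccBins, alffBins = alffBins,
              maxccTable = maxccTable, alffTable = alffTable, slopes = slopes)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    sp <- bold@spacingMm
    writeSeed(seed, file.path(outDir, "seed.txt"))
    writeLagMap(maxccMap, file.path(outDir, "maxcc"), sp)
    av <- alffArray(alffMap); av[is.na(av)] <- 0
    writeNiftiArray(av, file.path(outDir, "alff.nii.gz"), sp)
    writeDistributionTable(maxccTable, file.path(outDir, "distribution_maxcc.tsv"))
    writeDistributionTable(alffTable, file.path(outDir, "distribution_alff.tsv"))
    write.table(slopes, file.path(outDir, "slopes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeManifest(outDir, config,
                  list(subject = subjectId(bold),
                       n_valid_maxcc = nValid(maxccMap),
                       n_valid_alff = nValid(alffBins),
                       stages = c("smooth", "bandpass", "seed", "maxcc",
                                  "alff", "bin", "fractions", "slopes")))
  }
  res
}

#' Run the full cohort analysis
#'
#' Per-subject runs, group-averaged distribution graphs for both maps,
#' per-tissue slope-vs-zero tests, the bin-10-vs-9 contrasts for CSF and VA,
#' maxcc-vs-ALFF curve correlations, the swapped-seed null control, and the
#' true-vs-swapped slope contrast for GM and WM.
#'
#' @param cohort list of subjects, each a list with elements \code{bold} and
#'   \code{masks} (e.g. from [generateCohort()]).
#' @param config an [AnalysisConfig-class].
#' @param outDir optional output directory for tables and the manifest.
#' @return List with elements \code{subjects} (per-subject results),
#'   \code{groupMaxcc}, \code{groupAlff} ([GroupDistribution-class]),
#'   \code{slopeTests} (per-tissue, per-source data.frame),
#'   \code{binContrasts} (bin 10 vs 9 for CSF and VA),
#'   \code{curveCorrelations} (maxcc vs ALFF group curves per tissue),
#'   \code{swap} ([SwapResult-class]) and \code{trueVsSwap} (GM and WM).
#' @export
runCohort <- function(cohort, config = analysisConfig(), outDir = NULL) {
  if (length(cohort) < 2L)
    stopWith("cohort_size", "the cohort analysis needs at least 2 subjects")
  subjects <- lapply(cohort, function(s)
    runSubject(s$bold, s$masks, config))

  maxccTables <- lapply(subjects, `[[`, "maxccTable")
  alffTables <- lapply(subjects, `[[`, "alffTable")
  groupMaxcc <- averageDistributions(maxccTables)
  groupAlff <- averageDistributions(alffTables)

  tissues <- c("GM", "WM", "CSF", "VA")
  slopeTests <- do.call(rbind, lapply(tissues, function(tis) {
    do.call(rbind, lapply(c("maxcc", "alff"), function(srcName) {
      tabs <- if (srcName == "maxcc") maxccTables else alffTables
      sl <- vapply(tabs, function(t) fitDistributionSlope(t, tis)$slope, 0)
      r <- testSlopeNonzero(sl)
      data.frame(tissue = tis, sourceMap = srcName, meanSlope = mean(sl),
                 sdSlope = sd(sl), t = r$t, p = r$p, degenerate = r$degenerate)
    }))
  }))

  nb <- config@nBins
  binContrasts <- do.call(rbind, lapply(c("CSF", "VA"), function(tis) {
    r <- compareBins(maxccTables, tis, nb, nb - 1L)
    data.frame(tissue = tis, binA = nb, binB = nb - 1L, t = r$t, p = r$p,
               degenerate = r$degenerate)
  }))

  curveCorrelations <- vapply(tissues, function(tis)
    curveCorrelation(groupMaxcc, groupAlff, tis), 0)

  swapCohort <- lapply(seq_along(cohort), function(i)
    list(bold = subjects[[i]]$filtered, masks = cohort[[i]]$masks))
  swap <- swapSeedMaps(swapCohort, threshold = config@maxccThreshold,
                       lagLimitS = config@lagLimitS, nBins = nb,
                       keepMaps = FALSE, pooling = config@swapPooling)

  trueVsSwap <- do.call(rbind, lapply(c("GM", "WM"), function(tis) {
    trueSl <- vapply(maxccTables, function(t) fitDistributionSlope(t, tis)$slope, 0)
    swapSl <- swapSlopes(swap)
    swapSl <- swapSl$slope[swapSl$tissue == tis]
    if (length(swapSl) < 2L)
      return(data.frame(tissue = tis, t = NA_real_, p = NA_real_, degenerate = NA))
    r <- compareSlopeSets(trueSl, swapSl)
    data.frame(tissue = tis, t = r$t, p = r$p, degenerate = r$degenerate)
  }))

  res <- list(subjects = subjects, groupMaxcc = groupMaxcc,
              groupAlff = groupAlff, slopeTests = slopeTests,
              binContrasts = binContrasts,
              curveCorrelations = curveCorrelations, swap = swap,
              trueVsSwap = trueVsSwap)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeDistributionTable(groupMaxcc, file.path(outDir, "group_maxcc.tsv"))
    writeDistributionTable(groupAlff, file.path(outDir, "group_alff.tsv"))
    write.table(slopeTests, file.path(outDir, "slope_tests.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(binContrasts, file.path(outDir, "bin_contrasts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(tissue = tissues, r = unname(curveCorrelations)),
                file.path(outDir, "curve_correlations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(swap@slopeTests, file.path(outDir, "swap_slope_tests.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(trueVsSwap, file.path(outDir, "true_vs_swap.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeManifest(outDir, config,
                  list(n_subjects = length(cohort),
                       n_swap_maps = nrow(swapPairs(swap)),
                       n_swap_insufficient = swap@nInsufficient))
  }
  res
}
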