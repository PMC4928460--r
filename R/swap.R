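# Swapped-seed null control: recompute every subject's maxcc map using every
# other subject's seed regressor. With seeds that carry no information about
# the data subject, the surviving "valid" voxels reflect only the non-specific
# (SNR-driven) component, so their tissue-distribution curves should be flat.

#' Swapped-seed null control over a cohort
#'
#' For every ordered pair (i, j) with i != j, computes the maxcc map of
#' subject i's series against subject j's seed regressor (n * (n - 1) maps for
#' n subjects; 56 for the 8-subject design), builds a distribution table for
#' each map with at least \code{nBins} valid voxels, averages the tables, and
#' t-tests the per-map slopes against zero for each tissue.
#'
#' Maps with fewer valid voxels than bins are reported as insufficient rather
#' than failing the run. The validity threshold defaults to the same 0.3 used
#' for the true-seed maps; \code{threshold} can be lowered explicitly for
#' cohorts whose swapped maps are too clean to exercise.
#'
#' @param cohort list of subjects, each a list with elements \code{bold}
#'   (a preprocessed [BoldSeries-class]) and \code{masks}
#'   ([TissueMasks-class]), as returned by [generateCohort()] after
#'   preprocessing.
#' @param threshold minimum correlation for validity (default 0.3).
#' @param lagLimitS lag window half-width in seconds (default 6).
#' @param nBins bins for the distribution tables (default 10).
#' @param keepMaps retain the per-pair maps in the result (default TRUE).
#' @param pooling "per_map" treats each of the n(n-1) maps as a unit in the
#'   slope tests; "per_subject" first averages slopes within data subject.
#' @return A [SwapResult-class].
#' @export
swapSeedMaps <- function(cohort, threshold = 0.3, lagLimitS = 6.0, nBins = 10L,
                         keepMaps = TRUE, pooling = c("per_map", "per_subject")) {
  pooling <- match.arg(pooling)
  nSub <- length(cohort)
  if (nSub < 2L)
    stopWith("cohort_size", "the swap control needs at least 2 subjects, got %d", nSub)
  trs <- vapply(cohort, function(s) s$bold@trSeconds, 0)
  nts <- vapply(cohort, function(s) dim(s$bold@data)[4], 0L)
  if (max(abs(diff(trs))) > 1e-9 || length(unique(nts)) != 1L)
    stopWith("cohort_compat", "all subjects must share one TR and series length")

  seeds <- lapply(cohort, function(s)
    extractSeed(s$bold, maskArray(s$masks, "sss")))

  maps <- list(); tables <- list(); slopeRows <- list()
  pairRows <- list()
  m <- 0L
  for (i in seq_len(nSub)) {
    for (j in seq_len(nSub)) {
      if (i == j) next
      m <- m + 1L
      map <- computeMaxccMap(cohort[[i]]$bold, seeds[[j]],
                             brainMask(cohort[[i]]$masks),
                             threshold = threshold, lagLimitS = lagLimitS)
      nv <- nValid(map)
      used <- nv >= nBins
      if (used) {
        bins <- rankAndBin(maxccArray(map), validMask(map), nBins)
        tab <- binTissueFractions(bins, cohort[[i]]$masks,
                                  subjectId = subjectId(cohort[[i]]$bold),
                                  sourceMap = "maxcc_swap")
        tables[[length(tables) + 1L]] <- tab
        for (tis in c("GM", "WM", "CSF", "VA")) {
          sl <- fitDistributionSlope(tab, tis)
          sl$dataSubject <- i; sl$seedSubject <- j
          slopeRows[[length(slopeRows) + 1L]] <- sl
        }
      }
      if (keepMaps) maps[[m]] <- map
      pairRows[[m]] <- data.frame(dataSubject = i, seedSubject = j,
                                  nValid = nv, used = used)
    }
  }
  slopes <- if (length(slopeRows)) do.call(rbind, slopeRows) else
    data.frame(tissue = character(), slope = numeric(), intercept = numeric(),
               stderr = numeric(), subjectId = character(),
               dataSubject = integer(), seedSubject = integer())
  pairs <- do.call(rbind, pairRows)

  tests <- lapply(c("GM", "WM", "CSF", "VA"), function(tis) {
    s <- slopes$slope[slopes$tissue == tis]
    if (pooling == "per_subject" && length(s))
      s <- tapply(s, slopes$dataSubject[slopes$tissue == tis], mean)
    if (length(s) < 2L)
      return(data.frame(tissue = tis, t = NA_real_, p = NA_real_,
                        degenerate = NA, n = length(s)))
    r <- oneSampleT(as.numeric(s))
    data.frame(tissue = tis, t = r$t, p = r$p, degenerate = r$degenerate, n = r$n)
  })
  group <- if (length(tables) >= 2L) averageDistributions(tables) else NULL
  new("SwapResult", maps = maps, tables = tables, group = group,
      slopeTests = do.call(rbind, tests), slopes = slopes, pairs = pairs,
      nInsufficient = sum(!pairs$used))
}
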