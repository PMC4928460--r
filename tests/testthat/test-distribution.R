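flatMap <- function(vals, grid) array(vals, grid)

test_that("equal-count binning follows the ascending-rank remainder rule", {
  grid <- c(10, 10, 1)
  vm <- flatMap(sample(1:100), grid)
  bins <- rankAndBin(vm, array(TRUE, grid), 10)
  # values 1..10 land in bin 1, 91..100 in bin 10
  expect_true(all(binIndexArray(bins)[vm <= 10] == 1L))
  expect_true(all(binIndexArray(bins)[vm >= 91] == 10L))
  expect_equal(unname(tabulate(binIndexArray(bins), 10)), rep(10L, 10))

  # 103 voxels: remainder goes to the lowest-index bins
  grid2 <- c(103, 1, 1)
  vm2 <- flatMap(rnorm(103), grid2)
  bins2 <- rankAndBin(vm2, array(TRUE, grid2), 10)
  expect_equal(unname(tabulate(binIndexArray(bins2), 10)),
               c(11L, 11L, 11L, rep(10L, 7)))

  # all-tied values: stable break by voxel index, balanced bins
  vm3 <- flatMap(rep(1, 103), grid2)
  bins3 <- rankAndBin(vm3, array(TRUE, grid2), 10)
  expect_equal(binIndexArray(bins3)[, 1, 1],
               rep.int(1:10, c(11, 11, 11, rep(10, 7))))

  expect_error(rankAndBin(flatMap(rnorm(5), c(5, 1, 1)), array(TRUE, c(5, 1, 1)), 10),
               class = "slfomap_insufficient_voxels")
})

test_that("binning is invariant under strictly monotone transforms", {
  set.seed(20)
  grid <- c(8, 7, 3)
  vm <- flatMap(rnorm(prod(grid)), grid)
  valid <- flatMap(runif(prod(grid)) < 0.7, grid)
  b1 <- rankAndBin(vm, valid, 10)
  b2 <- rankAndBin(exp(2 * vm), valid, 10)
  expect_identical(binIndexArray(b1), binIndexArray(b2))
  expect_equal(sum(tabulate(binIndexArray(b1), 10)), sum(valid))
})

test_that("tissue fractions count exclusive labels within each bin", {
  # geometry: 20 voxels, 2 bins of 10; first bin all GM, second 5 GM + 5 WM
  grid <- c(20, 1, 1)
  vm <- flatMap(1:20, grid)
  gm <- flatMap(c(rep(TRUE, 15), rep(FALSE, 5)), grid)
  wm <- flatMap(c(rep(FALSE, 15), rep(TRUE, 5)), grid)
  othr <- flatMap(rep(FALSE, 20), grid)
  va <- flatMap(c(TRUE, rep(FALSE, 19)), grid)   # overlaps GM: precedence test
  sss <- va
  brain <- flatMap(rep(TRUE, 20), grid)
  csf <- flatMap(c(rep(FALSE, 19), TRUE), grid)
  wm <- wm & !csf
  masks <- TissueMasks(wm, gm, csf, va, brain, sss)
  bins <- rankAndBin(vm, brain, 2)
  tab <- binTissueFractions(bins, masks)
  f <- fractions(tab)
  expect_equal(rowSums(f), c(1, 1), tolerance = 1e-15)
  # VA precedence removed one GM voxel in bin 1
  expect_equal(unname(f[1, "GM"]), 0.9)
  expect_equal(unname(f[1, "VA"]), 0.1)
  expect_equal(unname(f[2, "GM"]), 0.5)
  expect_equal(unname(f[2, "WM"]), 0.4)
  expect_equal(unname(f[2, "CSF"]), 0.1)
})

test_that("distribution slope matches the closed-form OLS oracle", {
  f <- matrix(0, 10, 5)
  f[, 1] <- seq(0.1, 1.0, by = 0.1)          # exact line, slope 0.1
  f[, 5] <- 1 - f[, 1]
  tab <- tableFromFractions(f)
  est <- fitDistributionSlope(tab, "GM")
  expect_equal(est$slope, 0.1, tolerance = 1e-12)

  fl <- matrix(0.2, 10, 5); fl[, 5] <- 0.2   # constant: slope 0
  tabFlat <- tableFromFractions(fl / rowSums(fl))
  expect_equal(fitDistributionSlope(tabFlat, "WM")$slope, 0, tolerance = 1e-15)

  set.seed(21)
  y <- 0.3 + 0.02 * (1:10) + rnorm(10, sd = 0.01)
  fy <- cbind(y, 1 - y, 0, 0, 0)
  est2 <- fitDistributionSlope(tableFromFractions(fy), "GM")
  oracle <- olsOracle(y)
  expect_equal(est2$slope, unname(oracle["slope"]), tolerance = 1e-12)
  expect_equal(est2$intercept, unname(oracle["intercept"]), tolerance = 1e-12)
})

test_that("group averaging returns entrywise means and n-1 standard deviations", {
  set.seed(22)
  mk <- function() {
    f <- matrix(runif(50), 10, 5); tableFromFractions(f / rowSums(f))
  }
  t1 <- mk(); t2 <- mk()
  g <- averageDistributions(list(t1, t1))
  expect_equal(meanFractions(g), fractions(t1), tolerance = 1e-12)
  expect_true(all(sdFractions(g) == 0))

  g2 <- averageDistributions(list(t1, t2))
  expect_equal(meanFractions(g2), (fractions(t1) + fractions(t2)) / 2,
               tolerance = 1e-12)
  expect_equal(unname(sdFractions(g2)[3, 2]),
               sd(c(fractions(t1)[3, 2], fractions(t2)[3, 2])), tolerance = 1e-12)
  expect_equal(rowSums(meanFractions(g2)), rep(1, 10), tolerance = 1e-12)

  expect_error(averageDistributions(list(t1)), class = "slfomap_degenerate")
})

test_that("slope tests handle signal, null and degenerate inputs", {
  z <- testSlopeNonzero(rep(0, 5))
  expect_equal(z$t, 0); expect_equal(z$p, 1); expect_true(z$degenerate)

  d <- testSlopeNonzero(rep(0.1, 4))
  expect_equal(d$p, 0); expect_true(d$degenerate)

  set.seed(23)
  strong <- testSlopeNonzero(rnorm(8, mean = 1, sd = 0.05))
  expect_lt(strong$p, 1e-6)
  # agrees with stats::t.test on non-degenerate input
  x <- rnorm(8, 0.02, 0.03)
  expect_equal(testSlopeNonzero(x)$p, t.test(x, mu = 0)$p.value)

  eq <- compareSlopeSets(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0); expect_equal(eq$p, 1)
  sep <- compareSlopeSets(rep(0, 4), 1 + rnorm(4, sd = 0.01))
  expect_lt(sep$p, 1e-6)
  # matches the pooled-variance t.test
  a <- rnorm(6); b <- rnorm(7, 0.5)
  expect_equal(compareSlopeSets(a, b)$p, t.test(a, b, var.equal = TRUE)$p.value)
})

test_that("bin contrasts compare per-subject fractions between two bins", {
  set.seed(24)
  tabs <- lapply(1:8, function(i) {
    f <- matrix(runif(50, 0.1, 0.3), 10, 5)
    f[10, 4] <- f[9, 4] + 10 * 0.05          # bin 10 lifted by 10 sd units
    tableFromFractions(f / rowSums(f))
  })
  r <- compareBins(tabs, "VA", 10, 9)
  expect_lt(r$p, 0.001)
  same <- compareBins(tabs, "GM", 3, 3)
  expect_equal(same$p, 1)
  expect_error(compareBins(tabs, "VA", 11, 9), class = "slfomap_parameter")
})

test_that("curve correlation and quantile masks behave as a partition", {
  gm <- seq(0.20, 0.38, length.out = 10)
  f <- cbind(gm, 0.3, 0.1, 0.05, 1 - gm - 0.45)
  tab <- tableFromFractions(f)
  expect_equal(curveCorrelation(tab, tab, "GM"), 1, tolerance = 1e-12)
  # reflect the GM curve about its mean; rebalance the filler column
  gmNeg <- 2 * mean(gm) - gm
  neg <- cbind(gmNeg, 0.3, 0.1, 0.05, 1 - gmNeg - 0.45)
  expect_equal(curveCorrelation(tab, tableFromFractions(neg), "GM"), -1,
               tolerance = 1e-12)

  grid <- c(10, 6, 2)
  vm <- flatMap(rnorm(prod(grid)), grid)
  valid <- flatMap(runif(prod(grid)) < 0.8, grid)
  bins <- rankAndBin(vm, valid, 10)
  qm <- exportQuantileMasks(bins, 2)
  expect_length(qm, 5)
  expect_identical(Reduce(`|`, qm), valid)            # union is the valid mask
  expect_equal(sum(Reduce(`+`, lapply(qm, as.numeric))), sum(valid))  # disjoint
  expect_error(exportQuantileMasks(bins, 3), class = "slfomap_parameter")
})
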