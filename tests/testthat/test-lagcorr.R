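test_that("lagged Pearson matches a first-principles brute-force oracle", {
  set.seed(8)
  n <- 200; tr <- 0.72
  s <- rnorm(n); v <- rnorm(n)
  got <- laggedPearson(s, v, tr, 6)
  oracle <- bruteLagged(s, v, tr, 6)
  expect_equal(nrow(got), 17)  # k in -8..8 at TR 0.72
  expect_lt(max(abs(got$r - oracle$r)), 1e-10)
  expect_equal(got$lagS, oracle$lagS)

  # self-correlation peaks at lag zero with r = 1
  self <- laggedPearson(s, s, tr, 6)
  mx <- maxCorrelation(self)
  expect_equal(mx$maxcc, 1, tolerance = 1e-12)
  expect_equal(mx$lagS, 0)

  # an exact +3 TR delay (padded construction) gives r = 1 at lag 3 TR
  x <- rnorm(n + 3)
  seed <- x[4:(n + 3)]; voxel <- x[1:n]   # voxel(t) = seed(t - 3 TR)
  mx3 <- maxCorrelation(laggedPearson(seed, voxel, tr, 6))
  expect_equal(mx3$maxcc, 1, tolerance = 1e-9)
  expect_equal(mx3$lagS, 3 * tr, tolerance = 1e-12)

  expect_error(laggedPearson(s, v[-1], tr, 6), class = "slfomap_shape")
  # zero-variance overlap reports r = 0 with a degenerate flag
  z <- laggedPearson(rep(1, n), v, tr, 6)
  expect_true(all(z$r == 0) && all(z$degenerate))
})

test_that("maximum selection breaks ties by smallest |lag| then negative lag", {
  p1 <- data.frame(lagS = c(-0.72, 0, 0.72), r = c(0.2, 0.5, 0.4))
  expect_equal(maxCorrelation(p1), list(maxcc = 0.5, lagS = 0))
  p2 <- data.frame(lagS = c(-0.72, 0.72), r = c(0.5, 0.5))
  expect_equal(maxCorrelation(p2), list(maxcc = 0.5, lagS = -0.72))
  expect_error(maxCorrelation(data.frame(lagS = numeric(), r = numeric())),
               class = "slfomap_empty")
})

test_that("maxcc map equals the naive triple-loop implementation", {
  sp <- phantomSpec(gridShape = c(6, 6, 4), nTimepoints = 200L,
                    noiseSd = 1, rngSeed = 13L)
  ph <- generatePhantom(sp)
  filt <- bandpassFilter(ph$bold, 0.01, 0.15)
  seed <- extractSeed(filt, maskArray(ph$masks, "sss"))
  map <- computeMaxccMap(filt, seed, brainMask(ph$masks))
  oracle <- bruteMaxccMap(filt, seedValues(seed), brainMask(ph$masks),
                          0.72, 0.3, 6.0)
  ok <- brainMask(ph$masks)
  expect_lt(max(abs(maxccArray(map)[ok] - oracle$maxcc[ok])), 1e-10)
  expect_equal(lagArray(map)[ok], oracle$lagS[ok])
  expect_identical(validMask(map), oracle$valid)
})

test_that("noise-free unit-mixing phantom is exactly recovered", {
  sp <- tinySpec(gridShape = c(14, 14, 8), nTimepoints = 300L,
                 mixingFraction = c(wm = 1, gm = 1, csf = 1, va = 1, other = 1),
                 mixingJitter = 0, noiseSd = 0, lagRangeS = c(-4, 4),
                 cardiacAmplitude = c(wm = 0, gm = 0, csf = 0, va = 0,
                                      other = 0, arterial = 0))
  ph <- generatePhantom(sp)
  # seed directly from the planted sLFO: lag recovery is then absolute
  seed <- new("SeedTimecourse", values = slfoTimecourse(ph$truth),
              trSeconds = 0.72, sourceLabel = "truth", subjectId = "sub-01")
  map <- computeMaxccMap(ph$bold, seed, brainMask(ph$masks))
  ok <- brainMask(ph$masks)
  expect_true(all(validMask(map)[ok]))
  expect_equal(max(abs(maxccArray(map)[ok] - 1)), 0, tolerance = 1e-9)
  expect_identical(lagArray(map)[ok], trueLag(ph$truth)[ok])
})

test_that("validity requires maxcc strictly above the threshold", {
  set.seed(15)
  M <- matrix(rnorm(120 * 8), 120, 8)
  series <- seriesFromMatrix(M, c(2, 2, 2))
  roi <- array(FALSE, c(2, 2, 2)); roi[1, 1, 1] <- TRUE
  seed <- extractSeed(series, roi)
  brain <- array(TRUE, c(2, 2, 2))
  map0 <- computeMaxccMap(series, seed, brain, threshold = 0)
  cc <- maxccArray(map0)[2, 2, 2]
  # threshold set exactly at a voxel's maxcc: that voxel must be invalid
  mapEq <- computeMaxccMap(series, seed, brain, threshold = cc)
  expect_false(validMask(mapEq)[2, 2, 2])
  # a hair below: valid
  mapLt <- computeMaxccMap(series, seed, brain, threshold = cc - 1e-12)
  expect_true(validMask(mapLt)[2, 2, 2])
})

test_that("swapping seed and voxel negates the optimal lag", {
  set.seed(16)
  n <- 300; tr <- 0.72
  x <- rnorm(n + 20)
  a <- x[1:n]; b <- x[6:(n + 5)]  # exact 5-sample relative shift
  mab <- maxCorrelation(laggedPearson(a, b, tr, 6))
  mba <- maxCorrelation(laggedPearson(b, a, tr, 6))
  expect_equal(mab$maxcc, mba$maxcc, tolerance = 1e-10)
  expect_equal(mab$lagS, -mba$lagS, tolerance = 1e-10)
})

test_that("mean maxcc is non-decreasing in the planted mixing fraction", {
  set.seed(17)
  n <- 400; tr <- 0.72
  slfo <- makeSlfoTimecourse(n, tr, 0.01, 0.15, rngSeed = 99)
  levels <- seq(0.1, 0.9, by = 0.2)
  nPer <- 120
  M <- do.call(cbind, lapply(levels, function(a)
    a * slfo + matrix(rnorm(n * nPer, sd = 0.5), n, nPer)))
  series <- seriesFromMatrix(M, c(nPer, length(levels), 1))
  seed <- new("SeedTimecourse", values = slfo, trSeconds = tr,
              sourceLabel = "truth", subjectId = "x")
  map <- computeMaxccMap(series, seed, array(TRUE, c(nPer, length(levels), 1)),
                         threshold = 0)
  meansByLevel <- colMeans(matrix(maxccArray(map), nPer, length(levels)))
  expect_true(all(diff(meansByLevel) > 0))
})

test_that("TR and length mismatches are rejected", {
  set.seed(18)
  series <- seriesFromMatrix(matrix(rnorm(100 * 8), 100, 8), c(2, 2, 2))
  seedBadTr <- new("SeedTimecourse", values = rnorm(100), trSeconds = 1.0,
                   sourceLabel = "SSS", subjectId = "x")
  expect_error(computeMaxccMap(series, seedBadTr, array(TRUE, c(2, 2, 2))),
               class = "slfomap_sampling")
  seedBadLen <- new("SeedTimecourse", values = rnorm(90), trSeconds = 0.72,
                    sourceLabel = "SSS", subjectId = "x")
  expect_error(computeMaxccMap(series, seedBadLen, array(TRUE, c(2, 2, 2))),
               class = "slfomap_shape")
})
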