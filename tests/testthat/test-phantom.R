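test_that("sLFO generator is deterministic, band-limited and standardized", {
  s1 <- makeSlfoTimecourse(500, 0.72, 0.01, 0.15, rngSeed = 7)
  s2 <- makeSlfoTimecourse(500, 0.72, 0.01, 0.15, rngSeed = 7)
  expect_identical(s1, s2)
  expect_equal(mean(s1), 0, tolerance = 1e-12)
  expect_equal(sd(s1), 1, tolerance = 1e-12)

  power <- Mod(fft(s1))^2
  f <- (0:499) / (500 * 0.72)
  f <- pmin(f, 1 / 0.72 - f)
  inBand <- f >= 0.01 & f <= 0.15
  expect_gte(sum(power[inBand]) / sum(power), 0.99)

  # Nyquist at TR 10 s is 0.05 Hz, below the upper band edge
  expect_error(makeSlfoTimecourse(500, 10, 0.01, 0.15),
               class = "slfomap_invalid_band")
  expect_error(makeSlfoTimecourse(50, 0.72, 0.01, 0.15),
               class = "slfomap_invalid_length")
})

test_that("phantom masks obey the required algebra", {
  ph <- generatePhantom(tinySpec())
  m <- ph$masks
  expect_true(all(maskArray(m, "sss") <= maskArray(m, "va")))
  for (tis in c("wm", "gm", "csf", "va"))
    expect_true(all(maskArray(m, tis) <= brainMask(m)))
  # pairwise disjoint after the vessel-precedence rule
  overlap <- maskArray(m, "wm") + maskArray(m, "gm") +
    maskArray(m, "csf") + maskArray(m, "va")
  expect_lte(max(overlap), 1L)
  # ground-truth mixing ordered VA > GM > WM, zero outside the brain
  mix <- trueMixing(ph$truth)
  expect_gt(mean(mix[maskArray(m, "va")]), mean(mix[maskArray(m, "gm")]))
  expect_gt(mean(mix[maskArray(m, "gm")]), mean(mix[maskArray(m, "wm")]))
  expect_true(all(mix[!brainMask(m)] == 0))
  expect_true(all(abs(trueLag(ph$truth)) <= 6))
})

test_that("phantom generation is deterministic in the seed", {
  a <- generatePhantom(tinySpec(rngSeed = 9L))
  b <- generatePhantom(tinySpec(rngSeed = 9L))
  expect_identical(boldData(a$bold), boldData(b$bold))
  expect_identical(trueLag(a$truth), trueLag(b$truth))
  c <- generatePhantom(tinySpec(rngSeed = 10L))
  expect_false(identical(boldData(a$bold), boldData(c$bold)))
})

test_that("identity mixing with no noise or lag reproduces the sLFO exactly", {
  sp <- tinySpec(mixingFraction = c(wm = 1, gm = 1, csf = 1, va = 1, other = 1),
                 mixingJitter = 0, noiseSd = 0, lagRangeS = c(0, 0),
                 cardiacAmplitude = c(wm = 0, gm = 0, csf = 0, va = 0,
                                      other = 0, arterial = 0))
  ph <- generatePhantom(sp)
  slfo <- slfoTimecourse(ph$truth)
  idx <- which(brainMask(ph$masks))
  M <- matrix(boldData(ph$bold), prod(dim(brainMask(ph$masks))), 150)
  expect_equal(max(abs(sweep(M[idx, ], 2, slfo))), 0, tolerance = 1e-12)
})

test_that("zero mixing leaves pure noise with an all-zero mixing field", {
  sp <- tinySpec(mixingFraction = c(wm = 0, gm = 0, csf = 0, va = 0, other = 0),
                 noiseSd = 1)
  ph <- generatePhantom(sp)
  expect_true(all(trueMixing(ph$truth) == 0))
})

test_that("voxel correlation with the lag-aligned sLFO matches the closed form", {
  # r = a / sqrt(a^2 + c^2/2 + sigma^2) for signal a*L + c*cos + white noise,
  # checked by Monte-Carlo at n = 10000
  sp <- phantomSpec(gridShape = c(8, 8, 4), nTimepoints = 10000L,
                    mixingJitter = 0, noiseSd = 0.3,
                    cardiacAmplitude = c(wm = 0, gm = 0.4, csf = 0, va = 0,
                                         other = 0, arterial = 0),
                    lagRangeS = c(0, 0), rngSeed = 21L)
  ph <- generatePhantom(sp)
  gmIdx <- which(maskArray(ph$masks, "gm"))
  slfo <- slfoTimecourse(ph$truth)
  M <- matrix(boldData(ph$bold), prod(dim(brainMask(ph$masks))), 10000)
  a <- 0.5; cc <- 0.4; sig <- 0.3
  predicted <- a / sqrt(a^2 + cc^2 / 2 + sig^2)
  gmIdx <- head(gmIdx, 30)
  expect_gte(length(gmIdx), 10)
  got <- mean(vapply(gmIdx, function(v) cor(M[v, ], slfo), 0))
  expect_equal(got, predicted, tolerance = 0.02)
})

test_that("cohort subjects share geometry but carry independent sLFOs", {
  co <- generateCohort(8, tinySpec(nTimepoints = 500L), rngSeed = 3)
  expect_length(co, 8)
  for (i in 2:8)
    expect_identical(brainMask(co[[i]]$masks), brainMask(co[[1]]$masks))
  slfos <- vapply(co, function(s) slfoTimecourse(s$truth), numeric(500))
  cors <- cor(slfos)
  # band-limited signals have ~2*B*T ~ 100 effective samples at n = 500,
  # TR 0.72, so chance correlations scale as 1/sqrt(100), not 1/sqrt(500)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.35)
  expect_lt(abs(mean(cors[upper.tri(cors)])), 0.1)

  co2 <- generateCohort(3, tinySpec(), rngSeed = 5)
  co3 <- generateCohort(3, tinySpec(), rngSeed = 5)
  expect_identical(boldData(co2[[2]]$bold), boldData(co3[[2]]$bold))
  expect_error(generateCohort(1, tinySpec()), class = "slfomap_cohort_size")
})
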