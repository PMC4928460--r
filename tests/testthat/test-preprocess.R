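test_that("band-pass removes DC and matches the Butterworth response", {
  tr <- 0.72
  # constant input -> zero output (DC is outside the band)
  y0 <- bandpassFilter(rep(5, 300), 0.01, 0.15, trSeconds = tr)
  expect_lt(max(abs(y0)) / 5, 1e-8)

  # in-band tone: forward-backward gain equals the squared analog Butterworth
  # magnitude (bilinear warping is negligible this far below Nyquist)
  t <- (0:1999) * tr
  f <- 0.05
  y <- bandpassFilter(sin(2 * pi * f * t), 0.01, 0.15, trSeconds = tr)
  gain <- fitToneAmplitude(y[200:1800], f, tr)
  expect_equal(gain, butterAnalogGain2(f, 0.01, 0.15, 3), tolerance = 0.01)

  # out-of-band tone at 1 Hz, sampled at TR 0.2 s: attenuation equals the
  # designed digital filter's squared magnitude response (long series and a
  # central window so edge transients decay below the stopband floor)
  tr2 <- 0.2
  t2 <- (0:11999) * tr2
  y2 <- bandpassFilter(cos(2 * pi * 1.0 * t2), 0.01, 0.15, trSeconds = tr2)
  flt <- signal::butter(3, c(0.01, 0.15) * 2 * tr2, type = "pass")
  expected <- digitalGain2(flt$b, flt$a, 1.0, tr2)
  tmid <- (4000:8000) * tr2
  X <- cbind(cos(2 * pi * 1.0 * tmid), sin(2 * pi * 1.0 * tmid))
  got <- sqrt(sum(qr.coef(qr(X), y2[4001:8001])^2))
  expect_equal(got, expected, tolerance = 0.01 * expected)

  expect_error(bandpassFilter(rnorm(100), 0.01, 0.8, trSeconds = tr),
               class = "slfomap_invalid_band")
  expect_error(bandpassFilter(rnorm(10), 0.01, 0.15, trSeconds = tr),
               class = "slfomap_invalid_length")
})

test_that("zero-phase filtering is symmetric, linear and frequency-preserving", {
  set.seed(11)
  tr <- 0.72
  bp <- function(v) bandpassFilter(v, 0.01, 0.15, trSeconds = tr)
  # time reversal commutes with the zero-phase filter; tested on a signal
  # that is quiet at both ends so edge transients (shared by any filtfilt
  # with finite padding) stay below the tolerance
  core <- makeSlfoTimecourse(800, tr, 0.01, 0.15, rngSeed = 5)
  x <- c(rep(0, 800), core, rep(0, 800))
  expect_lt(max(abs(rev(bp(rev(x))) - bp(x))), 1e-8)
  # linearity
  y <- rnorm(length(x))
  expect_lt(max(abs(bp(2 * x + 3 * y) - (2 * bp(x) + 3 * bp(y)))), 1e-10)
  # an in-band tone keeps its spectral peak bin
  tone <- sin(2 * pi * 0.08 * (0:399) * tr)
  peak <- function(v) which.max(Mod(fft(v))[2:200])
  expect_identical(peak(bp(tone)), peak(tone))
})

test_that("filtering a 4D series equals filtering each voxel timecourse", {
  set.seed(3)
  M <- matrix(rnorm(120 * 24), 120, 24)
  series <- seriesFromMatrix(M, c(4, 3, 2))
  filt <- bandpassFilter(series, 0.01, 0.15)
  onevox <- bandpassFilter(M[, 7], 0.01, 0.15, trSeconds = 0.72)
  expect_equal(boldData(filt)[3, 2, 1, ], onevox, tolerance = 1e-12)
})

test_that("Gaussian smoothing matches the sampled kernel and conserves mass", {
  # single-voxel impulse at the volume centre, 1 mm spacing, FWHM 3 mm
  d <- c(15, 15, 15)
  arr <- array(0, c(d, 1)); arr[8, 8, 8, 1] <- 1
  series <- BoldSeries(arr, 0.72, spacingMm = c(1, 1, 1))
  sm <- spatialSmooth(series, 3.0)
  sigma <- 3 / (2 * sqrt(2 * log(2)))
  radius <- ceiling(4 * sigma)
  k1 <- exp(-((-radius):radius)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  expected <- array(0, d)
  for (i in -radius:radius) for (j in -radius:radius) for (l in -radius:radius)
    expected[8 + i, 8 + j, 8 + l] <-
      k1[i + radius + 1] * k1[j + radius + 1] * k1[l + radius + 1]
  expect_lt(max(abs(boldData(sm)[, , , 1] - expected)), 1e-6)
  expect_equal(sum(boldData(sm)), 1, tolerance = 1e-6)  # interior support

  # FWHM 0 is the identity; negative FWHM is rejected
  expect_identical(boldData(spatialSmooth(series, 0)), boldData(series))
  expect_error(spatialSmooth(series, -1), class = "slfomap_parameter")
})
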