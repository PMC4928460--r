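# Independent oracles and small fixtures used across the suite.

# Pearson r from first principles (sums of products), no call into the package
# or into cor().
pearsonOracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  if (den == 0) 0 else num / den
}

# Brute-force lagged correlation by explicit slicing.
bruteLagged <- function(seed, voxel, tr, lagLimitS) {
  n <- length(seed)
  kMax <- floor(lagLimitS / tr + 1e-9)
  do.call(rbind, lapply((-kMax):kMax, function(k) {
    if (k >= 0) { s <- seed[1:(n - k)]; v <- voxel[(1 + k):n] }
    else { s <- seed[(1 - k):n]; v <- voxel[1:(n + k)] }
    data.frame(lagS = k * tr, r = pearsonOracle(s, v))
  }))
}

# Naive triple-loop maxcc map: per voxel, brute-force lagged correlations and
# an explicit argmax with the smallest-|lag|, negative-first tie-break.
bruteMaxccMap <- function(series, seedValues, brain, tr, threshold, lagLimitS) {
  d <- dim(boldData(series))
  maxcc <- array(NA_real_, d[1:3]); lag <- array(NA_real_, d[1:3])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!brain[i, j, k]) next
    pr <- bruteLagged(seedValues, boldData(series)[i, j, k, ], tr, lagLimitS)
    ord <- order(-pr$r, abs(pr$lagS), pr$lagS)
    maxcc[i, j, k] <- pr$r[ord[1]]
    lag[i, j, k] <- pr$lagS[ord[1]]
  }
  list(maxcc = maxcc, lagS = lag, valid = !is.na(maxcc) & maxcc > threshold)
}

# Squared magnitude response (the forward-backward gain) of the analog
# order-n Butterworth band-pass prototype at frequency fHz.
butterAnalogGain2 <- function(fHz, lowHz, highHz, order) {
  w <- 2 * pi * fHz; w1 <- 2 * pi * lowHz; w2 <- 2 * pi * highHz
  h2 <- 1 / (1 + ((w^2 - w1 * w2) / (w * (w2 - w1)))^(2 * order))
  h2  # |H|^2: amplitude gain of one forward-backward pass
}

# Exact gain of the designed digital filter (forward-backward amplitude gain),
# from direct evaluation of the transfer polynomials on the unit circle.
digitalGain2 <- function(b, a, fHz, tr) {
  z <- exp(-1i * 2 * pi * fHz * tr)
  H <- sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1))
  Mod(H)^2
}

# Amplitude of a sinusoid at frequency f recovered by least squares.
fitToneAmplitude <- function(y, fHz, tr) {
  t <- (seq_along(y) - 1) * tr
  X <- cbind(cos(2 * pi * fHz * t), sin(2 * pi * fHz * t))
  sqrt(sum(qr.coef(qr(X), y)^2))
}

# OLS slope/intercept by the normal equations.
olsOracle <- function(y) {
  x <- seq_along(y)
  sl <- (length(x) * sum(x * y) - sum(x) * sum(y)) /
    (length(x) * sum(x^2) - sum(x)^2)
  c(slope = sl, intercept = mean(y) - sl * mean(x))
}

# Small phantom spec for fast tests.
tinySpec <- function(...) {
  args <- list(...)
  defaults <- list(gridShape = c(12L, 12L, 6L), nTimepoints = 150L, rngSeed = 42L)
  do.call(phantomSpec, utils::modifyList(defaults, args))
}

# Minimal BoldSeries from a time x voxel matrix laid out on a flat grid.
seriesFromMatrix <- function(M, gridShape, tr = 0.72) {
  stopifnot(ncol(M) == prod(gridShape))
  BoldSeries(array(t(M), c(gridShape, nrow(M))), trSeconds = tr)
}

# Distribution table built directly from a fractions matrix.
tableFromFractions <- function(f, subjectId = "s", sourceMap = "maxcc") {
  colnames(f) <- c("GM", "WM", "CSF", "VA", "other")
  new("DistributionTable", fractions = f, subjectId = subjectId,
      sourceMap = sourceMap)
}
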