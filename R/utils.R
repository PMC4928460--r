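# Internal helpers shared across modules.

#' @importFrom stats rnorm runif sd cor quantile pt lm coef mvfft t.test fft
#' @importFrom utils packageVersion write.table read.table combn
#' @importFrom signal butter
NULL

# Classed error so callers can condition on failure mode rather than message text.
stopWith <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(paste0("slfomap_", class), "slfomapError")))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's stream.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Flatten the spatial dimensions of a 4D array to a (voxel x time) matrix.
asVoxelMatrix <- function(data) {
  d <- dim(data)
  matrix(data, prod(d[1:3]), d[4])
}

checkSameGrid <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:3], dim(b)[1:3]))
    stopWith("shape", "%s are not on the same grid (%s vs %s)", what,
             paste(dim(a)[1:3], collapse = "x"), paste(dim(b)[1:3], collapse = "x"))
  invisible(TRUE)
}

nyquistHz <- function(trSeconds) 1 / (2 * trSeconds)

checkBand <- function(lowHz, highHz, trSeconds) {
  nyq <- nyquistHz(trSeconds)
  if (!(is.finite(lowHz) && is.finite(highHz) && lowHz > 0 &&
        lowHz < highHz && highHz < nyq))
    stopWith("invalid_band",
             "band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
             lowHz, highHz, nyq)
  invisible(TRUE)
}
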