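# Internal numeric and RNG helpers shared across modules.

#' Evaluate an expression under a private RNG stream
#'
#' Saves and restores the caller's `.Random.seed`, so simulator components can
#' be deterministic for a given seed without disturbing user-level RNG state.
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stream of child seeds from one master seed
#'
#' One global seed is expanded into per-module / per-tile seeds by drawing
#' integers below 2^31 from a stream seeded with the master seed. Documented
#' derivation so partial re-runs are reproducible.
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Round half away from zero
#'
#' Command-unit rounding convention: 0.5 units always rounds up in magnitude,
#' so +/- distances map to symmetric unit counts.
#' @noRd
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Sinc with the signal-processing normalization, sinc(0) = 1.
sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > .Machine$double.eps
  out[nz] <- sin(pi * x[nz]) / (pi * x[nz])
  out
}

#' Frequency coordinates of an n-point DFT in cycles/sample
#' @noRd
fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / n
}

#' Gaussian low-pass transfer function on an n1 x n2 DFT grid
#'
#' exp(-2 pi^2 sigma^2 f^2): the continuous Fourier transform of a unit-mass
#' Gaussian, sampled at DFT frequencies. sigma in pixels.
#' @noRd
gaussian_transfer <- function(n1, n2, sigma_px) {
  if (sigma_px <= 0) return(matrix(1, n1, n2))
  f1 <- fft_freq(n1)
  f2 <- fft_freq(n2)
  g1 <- exp(-2 * pi^2 * sigma_px^2 * f1^2)
  g2 <- exp(-2 * pi^2 * sigma_px^2 * f2^2)
  outer(g1, g2)
}

#' Bilinear interpolation of a matrix at fractional (row, col) coordinates
#'
#' Coordinates are 1-based like R indexing; queries outside the grid clamp to
#' the border value. `rows` and `cols` define a separable query grid.
#' @noRd
bilinear_grid <- function(m, rows, cols) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- pmin(pmax(floor(rows), 1), nr - 1L)
  c0 <- pmin(pmax(floor(cols), 1), nc - 1L)
  if (nr == 1L) r0 <- rep(1L, length(rows))
  if (nc == 1L) c0 <- rep(1L, length(cols))
  fr <- pmin(pmax(rows - r0, 0), 1)
  fc <- pmin(pmax(cols - c0, 0), 1)
  r1 <- pmin(r0 + 1L, nr)
  c1 <- pmin(c0 + 1L, nc)
  a <- m[r0, c0, drop = FALSE]
  b <- m[r1, c0, drop = FALSE]
  d <- m[r0, c1, drop = FALSE]
  e <- m[r1, c1, drop = FALSE]
  wfr <- matrix(fr, length(rows), length(cols))
  wfc <- matrix(fc, length(rows), length(cols), byrow = TRUE)
  a * (1 - wfr) * (1 - wfc) + b * wfr * (1 - wfc) +
    d * (1 - wfr) * wfc + e * wfr * wfc
}

#' Sobel gradient magnitude squared, interior pixels only
#' @noRd
sobel_sq <- function(im) {
  nr <- nrow(im); nc <- ncol(im)
  if (nr < 3 || nc < 3) return(matrix(0, 0, 0))
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  gx <- (im[i - 1, j + 1] + 2 * im[i, j + 1] + im[i + 1, j + 1]) -
        (im[i - 1, j - 1] + 2 * im[i, j - 1] + im[i + 1, j - 1])
  gy <- (im[i + 1, j - 1] + 2 * im[i + 1, j] + im[i + 1, j + 1]) -
        (im[i - 1, j - 1] + 2 * im[i - 1, j] + im[i - 1, j + 1])
  gx^2 + gy^2
}

#' Next FFT-friendly size >= n (factors limited to 2, 3, 5, 7)
#' @noRd
next_fft_size <- function(n) {
  smooth <- function(m) {
    for (p in c(2, 3, 5, 7)) while (m %% p == 0) m <- m / p
    m == 1
  }
  while (!smooth(n)) n <- n + 1
  as.integer(n)
}

#' Gaussian blur of a matrix via the FFT (circular boundary)
#' @noRd
fft_gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  G <- gaussian_transfer(nrow(m), ncol(m), sigma_px)
  Re(stats::fft(stats::fft(m) * G, inverse = TRUE)) / length(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
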