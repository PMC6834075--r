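#' @include phaseCT-package.R
NULL

## Run expr with a temporary RNG state seeded by `seed`; NULL/NA leaves the
## RNG untouched. Restores the caller's .Random.seed afterwards.
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

## DFT sample frequencies in cycles per unit length (zero frequency first),
## matching the layout of stats::fft output.
.fftFreq <- function(n, d = 1) {
  half <- floor(n / 2)
  k <- c(seq.int(0L, ceiling(n / 2) - 1L),
         if (half >= 1L) seq.int(-half, -1L))
  k / (n * d)
}

## 2D FFT helpers (stats::fft is N-dimensional for arrays)
.fft2 <- function(x) stats::fft(x)
.ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

## |f|^2 grid for an nr x nc matrix with the given pitch (cycles^2 / m^2)
.freqSqGrid <- function(nr, nc, pitch) {
  fr <- .fftFreq(nr, pitch)
  fc <- .fftFreq(nc, pitch)
  outer(fr^2, fc^2, `+`)
}

## Gaussian blur through the Fourier domain; sigma in pixels (scalar or
## c(sigmaRow, sigmaCol)). Exactly mean-preserving (zero-frequency gain 1).
.gaussianBlurFFT <- function(x, sigma) {
  if (all(sigma <= 0)) return(x)
  sigma <- rep(sigma, length.out = 2L)
  nr <- nrow(x); nc <- ncol(x)
  fr <- .fftFreq(nr)
  fc <- .fftFreq(nc)
  otf <- exp(-2 * pi^2 * (outer(sigma[1]^2 * fr^2, sigma[2]^2 * fc^2, `+`)))
  Re(.ifft2(.fft2(x) * otf))
}

## Otsu threshold of a numeric vector (256-bin histogram)
.otsu <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / diff(r) * nbins)),
                nbins = nbins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mT <- m0[nbins]
  sb <- (mT * w0 - m0)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

## Sub-sample peak position by parabolic interpolation around index i0 of y;
## returns fractional index (1-based).
.parabolicPeak <- function(y, i0 = which.max(y)) {
  n <- length(y)
  if (i0 <= 1L || i0 >= n) return(as.numeric(i0))
  den <- y[i0 - 1L] - 2 * y[i0] + y[i0 + 1L]
  if (den == 0) return(as.numeric(i0))
  i0 + 0.5 * (y[i0 - 1L] - y[i0 + 1L]) / den
}

## circular cross-correlation of two equal-length vectors via FFT; returns
## correlation for lags 0..n-1 (lag k: b shifted by +k matches a)
.circCorr <- function(a, b) {
  n <- length(a)
  Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) / n
}

## contrast-to-noise ratio between two masked regions of an image/volume
#' Contrast-to-noise ratio between two regions
#'
#' CNR = |mean(A) - mean(B)| / sd(B), the usual figure for how clearly a
#' feature (A) stands out of its surroundings (B).
#'
#' @param x numeric array
#' @param maskA logical array selecting the feature voxels/pixels
#' @param maskB logical array selecting the reference (background) region
#' @return scalar CNR
#' @export
contrastToNoise <- function(x, maskA, maskB) {
  a <- x[maskA]; b <- x[maskB]
  if (length(a) == 0 || length(b) < 2) stop("empty region mask")
  abs(mean(a) - mean(b)) / stats::sd(b)
}
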