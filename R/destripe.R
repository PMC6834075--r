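#' @include pipeline.R
NULL

## Periodized Daubechies-4 (two vanishing moments) filter pair
.DB4_H <- {
  s3 <- sqrt(3)
  c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
}
.DB4_G <- rev(.DB4_H) * c(1, -1, 1, -1)

## one periodized analysis step along columns of x (even nrow):
## returns list(a, d) each with nrow/2 rows
.dwtCols <- function(x) {
  n <- nrow(x)
  idx <- function(s) ((seq(1, n, by = 2) + s - 1L) %% n) + 1L
  a <- 0; d <- 0
  for (t in 0:3) {
    xs <- x[idx(t), , drop = FALSE]
    a <- a + .DB4_H[t + 1] * xs
    d <- d + .DB4_G[t + 1] * xs
  }
  list(a = a, d = d)
}

## inverse of .dwtCols
.idwtCols <- function(a, d) {
  n2 <- nrow(a)
  n <- 2L * n2
  out <- matrix(0, n, ncol(a))
  pos <- seq(1, n, by = 2)
  for (t in 0:3) {
    rows <- ((pos + t - 1L) %% n) + 1L
    out[rows, ] <- out[rows, ] + .DB4_H[t + 1] * a + .DB4_G[t + 1] * d
  }
  out
}

## full separable 2D analysis step: returns LL, LH, HL, HH where the first
## letter is the row (vertical) channel and the second the column channel
.dwt2 <- function(x) {
  rowsplit <- .dwtCols(x)
  la <- .dwtCols(t(rowsplit$a))
  ld <- .dwtCols(t(rowsplit$d))
  list(LL = t(la$a), LH = t(la$d), HL = t(ld$a), HH = t(ld$d))
}

.idwt2 <- function(b) {
  a <- t(.idwtCols(t(b$LL), t(b$LH)))
  d <- t(.idwtCols(t(b$HL), t(b$HH)))
  .idwtCols(a, d)
}

#' Wavelet-Fourier destriping of a sinogram
#'
#' Removes vertical stripes (detector-column offsets, which reconstruct into
#' ring artifacts) by the wavelet-Fourier method: the sinogram is decomposed
#' with a separable Daubechies-4 wavelet; in each band carrying horizontal
#' high-pass detail (vertical structure), the Fourier coefficients along the
#' angle axis are damped by 1 - exp(-k^2 / (2 sigma^2)) around zero
#' frequency, suppressing angle-invariant (striped) content; the sinogram is
#' then reconstructed.
#'
#' @param sinogram a \linkS4class{Sinogram} or numeric matrix
#'   (angles x detector columns, >= 2 rows)
#' @param levels decomposition depth (clamped, with a warning, to what the
#'   sinogram supports)
#' @param sigma damping width in frequency samples
#' @return same type as the input
#' @export
destripe <- function(sinogram, levels = 4L, sigma = 2) {
  isS4in <- is(sinogram, "Sinogram")
  x <- if (isS4in) sinogram@data else sinogram
  if (nrow(x) < 2L) stop("sinogram needs at least 2 rows")
  maxLev <- floor(log2(min(nrow(x), ncol(x)))) - 1L
  if (levels > maxLev) {
    warning(sprintf("levels clamped from %d to %d for a %d x %d sinogram",
                    levels, maxLev, nrow(x), ncol(x)))
    levels <- maxLev
  }
  block <- 2^levels
  padTo <- function(n) ceiling(n / block) * block
  nr <- nrow(x); nc <- ncol(x)
  pr <- padTo(nr); pc <- padTo(nc)
  # reflective padding to a multiple of 2^levels
  ri <- c(seq_len(nr), nr - seq_len(pr - nr) + 1L)
  ci <- c(seq_len(nc), nc - seq_len(pc - nc) + 1L)
  xp <- x[ri, ci, drop = FALSE]

  damp <- function(band) {
    nb <- nrow(band)
    k <- .fftFreq(nb) * nb
    m <- 1 - exp(-k^2 / (2 * sigma^2))
    sp <- stats::mvfft(band)
    Re(stats::mvfft(sp * m, inverse = TRUE)) / nb
  }
  rec <- function(y, lev) {
    if (lev == 0L) return(y)
    b <- .dwt2(y)
    b$LL <- rec(b$LL, lev - 1L)
    # vertical structure = low-pass along rows (angles), high-pass along
    # columns (detector): the LH band; damp its angle-axis spectrum
    b$LH <- damp(b$LH)
    .idwt2(b)
  }
  out <- rec(xp, levels)[seq_len(nr), seq_len(nc), drop = FALSE]
  if (isS4in)
    new("Sinogram", data = out, angles = sinogram@angles,
        center = sinogram@center)
  else out
}
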