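#' @include pipeline.R
NULL

#' Find the center of rotation of a projection series
#'
#' With the sample rotated by (almost) 180 degrees between the first and last
#' projection, the last projection mirrored about the vertical axis matches
#' the first one up to a horizontal shift of twice the axis offset. The shift
#' is found by circular cross-correlation of the vertically averaged
#' profiles, refined to sub-pixel precision by parabolic interpolation of the
#' correlation peak. Needed because absolute rotation angles are typically
#' not registered by the camera clock.
#'
#' @param x a \linkS4class{ProjectionStack} or 3D array
#'   (rows x detector columns x angles) of retrieved/corrected projections
#' @param anglesDeg rotation angles (required when x is a plain array)
#' @return center of rotation as a 0-based detector pixel coordinate, with a
#'   warning when the correlation peak sits at the search boundary
#' @export
findCenter <- function(x, anglesDeg = NULL) {
  if (is(x, "ProjectionStack")) {
    anglesDeg <- x@angles
    x <- x@frames
  }
  if (is.null(anglesDeg)) stop("anglesDeg required for a plain array")
  span <- max(anglesDeg) - min(anglesDeg)
  if (span < 179)
    stop(sprintf("stack spans only %.4g degrees; >= 179 required", span))
  first <- colMeans(x[, , 1])
  last <- colMeans(x[, , dim(x)[3]])
  a <- first - mean(first)
  b <- rev(last) - mean(last)
  cc <- .circCorr(a, b)
  n <- length(a)
  i0 <- which.max(cc)
  ip <- .parabolicPeak(cc, i0)
  lag <- ip - 1
  if (lag > n / 2) lag <- lag - n
  if (abs(lag) > 0.4 * n)
    warning("correlation peak near the search boundary; center unreliable")
  (n - 1) / 2 + lag / 2
}

#' Extract per-slice sinograms from a projection array
#'
#' @param x 3D array (rows x detector columns x angles), e.g. the
#'   \code{thickness} array from \code{\link{processStack}}
#' @param anglesDeg rotation angles (degrees)
#' @param center center of rotation (0-based pixels) or NA
#' @param slices which rows (vertical slices) to extract; default all
#' @return list of \linkS4class{Sinogram}
#' @export
makeSinograms <- function(x, anglesDeg, center = NA_real_,
                          slices = seq_len(dim(x)[1])) {
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == length(anglesDeg))
  lapply(slices, function(v)
    new("Sinogram", data = t(x[v, , ]), angles = anglesDeg,
        center = center))
}

## Shepp-Logan filtered ramp applied along the detector axis of an
## (angles x nu) sinogram; returns the filtered sinogram (same shape).
## Frequencies in cycles/m so the backprojection yields attenuation (1/m).
.filterSino <- function(sino, pitch) {
  na <- nrow(sino); nu <- ncol(sino)
  np <- 2^ceiling(log2(2 * nu))
  fN <- 1 / (2 * pitch)
  f <- .fftFreq(np, pitch)
  H <- (2 * fN / pi) * abs(sin(pi * f / (2 * fN)))
  padded <- matrix(0, np, na)
  padded[seq_len(nu), ] <- t(sino)
  sp <- stats::mvfft(padded) * H
  q <- Re(stats::mvfft(sp, inverse = TRUE)) / np
  t(q[seq_len(nu), , drop = FALSE])
}

#' Filtered backprojection reconstruction
#'
#' Slice-wise parallel-beam filtered backprojection with the Shepp-Logan
#' filter (band-limited ramp |f| sinc(f / 2f_N)) and linear interpolation in
#' the backprojection. Gray values come out proportional to the local
#' attenuation coefficient (1/m) of whatever quantity the sinograms hold;
#' no absolute calibration is attempted.
#'
#' @param sinograms a \linkS4class{Sinogram}, a list of them (one per
#'   vertical slice), or a 3D projection array (with \code{anglesDeg})
#' @param anglesDeg angles when a plain array is given
#' @param center center of rotation (0-based pixels); defaults to the stored
#'   sinogram center, or the grid center when unset
#' @param pitch detector pixel pitch (m)
#' @return a \linkS4class{Tomogram} of dimension (nu, nu, nSlices)
#' @export
reconstruct <- function(sinograms, anglesDeg = NULL, center = NULL,
                        pitch) {
  if (is(sinograms, "Sinogram")) sinograms <- list(sinograms)
  if (is.matrix(sinograms)) {
    if (is.null(anglesDeg)) stop("anglesDeg required for a plain matrix")
    sinograms <- list(new("Sinogram", data = sinograms, angles = anglesDeg,
                          center = if (is.null(center)) NA_real_ else
                            center))
  }
  if (is.array(sinograms) && length(dim(sinograms)) == 3L) {
    if (is.null(anglesDeg)) stop("anglesDeg required for a plain array")
    sinograms <- makeSinograms(sinograms, anglesDeg,
                               if (is.null(center)) NA_real_ else center)
  }
  s1 <- sinograms[[1]]
  ang <- s1@angles
  if (length(ang) > 1L) {
    st <- diff(ang)
    if (any(abs(st - st[1]) > 1e-6 * abs(st[1])))
      stop("non-uniform angles")
  }
  nu <- ncol(s1@data)
  ctr <- if (!is.null(center)) center else
    if (!is.na(s1@center)) s1@center else (nu - 1) / 2
  thetas <- ang * pi / 180
  nsl <- length(sinograms)
  vol <- array(0, c(nu, nu, nsl))
  for (v in seq_len(nsl)) {
    filt <- .filterSino(sinograms[[v]]@data, pitch)
    vol[, , v] <- cpp_backproject(filt, thetas, ctr, nu) *
      (pi / length(thetas))
  }
  new("Tomogram", data = vol, voxelSize = pitch)
}
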