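#' @include utils.R materials.R
NULL

## Gaussian window for SSIM (11 taps, sigma 1.5, normalized)
.ssimKernel <- function(sigma = 1.5, half = 5L) {
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k / sum(k)
}

## local mean/variance statistics reused across many SSIM evaluations
.ssimStats <- function(x, kernel) {
  mu <- cpp_sepconv2(x, kernel)
  list(x = x, mu = mu, v = cpp_sepconv2(x * x, kernel) - mu^2)
}

.ssimFromStats <- function(sa, sb, C1, C2, kernel) {
  cab <- cpp_sepconv2(sa$x * sb$x, kernel) - sa$mu * sb$mu
  s <- ((2 * sa$mu * sb$mu + C1) * (2 * cab + C2)) /
    ((sa$mu^2 + sb$mu^2 + C1) * (sa$v + sb$v + C2))
  mean(s)
}

#' Structural similarity index
#'
#' Mean SSIM over the image with the conventional parameterization: Gaussian
#' window (sigma 1.5, 11 taps), K1 = 0.01, K2 = 0.03, C_i = (K_i * dataRange)^2.
#'
#' @param a,b numeric matrices of equal shape
#' @param dataRange dynamic range; default is the value range spanned by both
#'   images together
#' @param K1,K2 stability constants
#' @param sigma Gaussian window sigma (pixels)
#' @return scalar in [-1, 1]
#' @export
ssim <- function(a, b, dataRange = NULL, K1 = 0.01, K2 = 0.03, sigma = 1.5) {
  if (!all(dim(a) == dim(b))) stop("a and b must have the same shape")
  if (is.null(dataRange)) dataRange <- diff(range(c(a, b)))
  if (dataRange <= 0) dataRange <- 1
  k <- .ssimKernel(sigma)
  .ssimFromStats(.ssimStats(a, k), .ssimStats(b, k),
                 (K1 * dataRange)^2, (K2 * dataRange)^2, k)
}

## normalized flats with cached SSIM statistics; data range from the pool
.prepFlatPool <- function(flats) {
  mats <- lapply(flats, function(f)
    if (is(f, "Hologram") || is(f, "FlatField")) f@data else f)
  norm <- lapply(mats, function(m) m / mean(m))
  kernel <- .ssimKernel()
  list(mats = mats,
       stats = lapply(norm, .ssimStats, kernel = kernel),
       dataRange = diff(range(unlist(lapply(norm, range)))),
       kernel = kernel)
}

.selectFlat <- function(img, pool, K1 = 0.01, K2 = 0.03) {
  dr <- if (pool$dataRange > 0) pool$dataRange else 1
  C1 <- (K1 * dr)^2; C2 <- (K2 * dr)^2
  si <- .ssimStats(img / mean(img), pool$kernel)
  vapply(pool$stats, function(sf)
    .ssimFromStats(si, sf, C1, C2, pool$kernel), numeric(1))
}

#' Flat-field correction with SSIM-based flat selection
#'
#' Divides the image by the flat field most similar to it, similarity being
#' the mean SSIM between the mean-normalized image and each mean-normalized
#' flat (mean normalization makes the choice invariant to global intensity
#' scaling). This follows the practice of collecting a pool of sample-free
#' images and correcting each projection with its best match.
#'
#' @param image a \linkS4class{Hologram} or numeric matrix
#' @param flats list of \linkS4class{Hologram}, \linkS4class{FlatField} or
#'   matrices (at least one)
#' @return list with \code{corrected} (matrix, dimensionless transmission),
#'   \code{index} (chosen flat) and \code{ssim} (similarity per flat)
#' @export
flatCorrect <- function(image, flats) {
  img <- if (is(image, "Hologram")) image@data else image
  if (length(flats) < 1L) stop("at least one flat field required")
  pool <- .prepFlatPool(flats)
  mats <- pool$mats
  if (!all(vapply(mats, function(m) all(dim(m) == dim(img)), logical(1))))
    stop("flat shapes must match the image")
  sims <- .selectFlat(img, pool)
  k <- which.max(sims)
  flat <- mats[[k]]
  # image/flat is already transmission when both were taken at the same
  # exposure; guard against (improbable) zero-count flat pixels
  floorv <- 1e-6 * mean(flat)
  corrected <- img / pmax(flat, floorv)
  list(corrected = corrected, index = k, ssim = sims)
}

#' Contrast-matched retrieval ratio for a two-material interface
#'
#' Paganin retrieval assumes a single material with ratio delta/beta. When
#' the goal is to render the interface between an inclusion and its matrix
#' faithfully, the appropriate ratio is that of the property differences,
#' (delta_A - delta_B) / (beta_A - beta_B): with this value the retrieval
#' inverts the phase contrast generated by the inclusion-matrix interface
#' exactly (to first order). Empirical ratios tuned on real detector data
#' (such as the 5e3 used for crystals in LCP) fold in additional instrument
#' response and need not match this physical value.
#'
#' @param materialA inclusion material id
#' @param materialB matrix material id
#' @param energyKeV photon energy (keV)
#' @return dimensionless delta/beta ratio
#' @examples
#' contrastDeltaOverBeta("protein", "lcp", 12.7)
#' @export
contrastDeltaOverBeta <- function(materialA, materialB, energyKeV) {
  a <- opticalConstants(materialA, energyKeV)
  b <- opticalConstants(materialB, energyKeV)
  if (a@beta == b@beta) stop("materials have identical beta; ratio undefined")
  (a@delta - b@delta) / (a@beta - b@beta)
}

#' Paganin single-distance phase retrieval
#'
#' Inverts a single propagated image of a (quasi) single-material object into
#' a thickness-proportional map:
#' t = -(1/mu) ln( invFT[ FT[I/I0] / (1 + pi lambda z (delta/beta) |f|^2) ] )
#' with spatial frequencies in cycles per metre and mu = 4 pi beta / lambda
#' taken from the reference material. (The widely printed form with
#' lambda z delta/(4 pi beta) |k|^2 is identical with |k| = 2 pi |f|.)
#' I0 is taken as 1 after flat correction. Non-positive filtered values are
#' clipped to \code{floor}; the number of clipped pixels is returned in the
#' \code{"clipped"} attribute.
#'
#' @param corrected flat-corrected intensity matrix (I/I0)
#' @param deltaOverBeta retrieval ratio delta/beta (dimensionless); the
#'   empirically favoured value for crystals in LCP is 5e3
#' @param z propagation distance (m)
#' @param energyKeV photon energy (keV)
#' @param pitch pixel pitch (m)
#' @param material reference material supplying mu (default water)
#' @param floor clip floor for the filtered intensity
#' @return thickness map (m) with attribute \code{clipped}
#' @export
paganinRetrieve <- function(corrected, deltaOverBeta = 5e3, z, energyKeV,
                            pitch, material = "water", floor = 1e-6) {
  if (z <= 0 || pitch <= 0) stop("z and pitch must be positive")
  lambda <- wavelengthFromEnergy(energyKeV)
  mu <- opticalConstants(material, energyKeV)@mu
  f2 <- .freqSqGrid(nrow(corrected), ncol(corrected), pitch)
  filt <- 1 / (1 + pi * lambda * z * deltaOverBeta * f2)
  sm <- Re(.ifft2(.fft2(corrected) * filt))
  nclip <- sum(sm < floor)
  sm <- pmax(sm, floor)
  out <- -log(sm) / mu
  attr(out, "clipped") <- nclip
  out
}

#' Retrieve thickness maps for a whole projection stack
#'
#' Convenience wrapper: flat-corrects every frame against the flat pool and
#' applies \code{\link{paganinRetrieve}}.
#'
#' @param stack a \linkS4class{ProjectionStack} of recorded counts
#' @param flats list of recorded flat images (see \code{\link{flatCorrect}})
#' @param deltaOverBeta,material,floor passed to \code{\link{paganinRetrieve}}
#' @return list with \code{thickness} (3D array), \code{flatIndex} (chosen
#'   flat per frame) and \code{clipped} (clip counts per frame)
#' @export
processStack <- function(stack, flats, deltaOverBeta = 5e3,
                         material = "water", floor = 1e-6) {
  stopifnot(is(stack, "ProjectionStack"))
  d <- dim(stack@frames)
  pool <- .prepFlatPool(flats)
  # precompute the Paganin filter and mu once for the whole stack
  lambda <- wavelengthFromEnergy(stack@energy)
  mu <- opticalConstants(material, stack@energy)@mu
  f2 <- .freqSqGrid(d[1], d[2], stack@pitch)
  filt <- 1 / (1 + pi * lambda * stack@z * deltaOverBeta * f2)
  out <- array(0, d)
  idx <- integer(d[3])
  ncl <- integer(d[3])
  for (a in seq_len(d[3])) {
    img <- stack@frames[, , a]
    sims <- .selectFlat(img, pool)
    k <- which.max(sims)
    flat <- pool$mats[[k]]
    corrected <- img / pmax(flat, 1e-6 * mean(flat))
    sm <- Re(.ifft2(.fft2(corrected) * filt))
    ncl[a] <- sum(sm < floor)
    out[, , a] <- -log(pmax(sm, floor)) / mu
    idx[a] <- k
  }
  list(thickness = out, flatIndex = idx, clipped = ncl)
}
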