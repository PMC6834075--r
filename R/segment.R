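#' @include recon.R
NULL

## separable 3D Gaussian blur through the Fourier domain
.gaussianBlur3 <- function(x, sigma) {
  if (all(sigma <= 0)) return(x)
  sigma <- rep(sigma, length.out = 3L)
  d <- dim(x)
  otf1 <- function(n, s) if (s > 0) exp(-2 * pi^2 * s^2 * .fftFreq(n)^2) else
    rep(1, n)
  otf <- outer(outer(otf1(d[1], sigma[1]), otf1(d[2], sigma[2])),
               otf1(d[3], sigma[3]))
  Re(stats::fft(stats::fft(x) * otf, inverse = TRUE)) / length(x)
}

## centroid table of an integer label volume; optional non-negative weights
## give intensity-weighted centroids
.regionTable <- function(lab, weights = NULL) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L)
    return(data.frame(label = integer(0), voxels = integer(0),
                      cx = numeric(0), cy = numeric(0), cz = numeric(0)))
  d <- dim(lab)
  l <- lab[idx]
  k <- idx - 1L
  xi <- k %% d[1] + 1L
  yi <- (k %/% d[1]) %% d[2] + 1L
  zi <- k %/% (d[1] * d[2]) + 1L
  labs <- sort(unique(l))
  w <- if (is.null(weights)) rep(1, length(idx)) else weights[idx]
  wt <- as.vector(tapply(w, l, sum))
  bad <- !is.finite(wt) | wt <= 0
  if (any(bad)) {  # fall back to unweighted for all-zero-weight regions
    w[l %in% labs[bad]] <- 1
    wt <- as.vector(tapply(w, l, sum))
  }
  data.frame(label = labs,
             voxels = as.integer(tabulate(l)[labs]),
             cx = as.vector(tapply(w * xi, l, sum)) / wt,
             cy = as.vector(tapply(w * yi, l, sum)) / wt,
             cz = as.vector(tapply(w * zi, l, sum)) / wt,
             row.names = NULL)
}

#' Segment a tomogram into bright regions
#'
#' Non-interactive segmentation of reconstructed crystals: optional Gaussian
#' denoising, thresholding, 6-connected components, and filtering by size and
#' border contact. With seeds, a seeded watershed (priority flood on the
#' gradient magnitude) refines the partition of the foreground instead.
#'
#' Threshold rules:
#' \describe{
#'   \item{inclusions}{detector for small dense inclusions (crystals) in a
#'     large matrix with a smooth but strong reconstruction background. The
#'     volume is band-passed (subtracting a Gaussian background of width
#'     \code{backgroundSigma}), standardized by a running local mean/sd over
#'     a window of width \code{windowSigma}, and thresholded at local
#'     z-score \code{k}; the material mask (Otsu air/material, slightly
#'     eroded) confines the search and suppresses boundary rims. Region
#'     centroids are intensity-weighted by the band-passed signal.}
#'   \item{otsu}{single Otsu threshold over the whole volume, for data that
#'     really are bimodal (bright objects on a dark background).}
#'   \item{robust}{median + k * MAD of the gray values, k acting on the
#'     global scale.}
#' }
#'
#' @param tomogram a \linkS4class{Tomogram} (or 3D array with voxel size 1)
#' @param rule threshold rule, or use \code{threshold} directly
#' @param threshold explicit threshold (overrides \code{rule})
#' @param k threshold multiplier: local z-score for "inclusions", MAD
#'   multiplier for "robust"
#' @param kPeak for "inclusions": minimum peak local z-score a region must
#'   reach to be kept (hysteresis; regions merely hovering at the mask
#'   threshold are artifacts)
#' @param minSize minimum region size in voxels
#' @param maxSize maximum region size in voxels (Inf keeps everything;
#'   useful when the expected inclusion size is known from the experiment)
#' @param smoothSigma Gaussian denoising sigma in voxels (0 = none)
#' @param backgroundSigma background scale (voxels) for "inclusions"
#' @param windowSigma local-statistics window (voxels) for "inclusions"
#' @param excludeEdges drop regions touching the volume border (mount frames
#'   and truncated structures reach the border by construction)
#' @param seeds optional integer array of seed labels for the watershed
#' @return a \linkS4class{LabelVolume}; empty (with a warning) when no
#'   foreground survives
#' @export
segment <- function(tomogram, rule = c("inclusions", "otsu", "robust"),
                    threshold = NULL, k = 2.5, kPeak = 4, minSize = 20L,
                    maxSize = Inf, smoothSigma = 1, backgroundSigma = 5,
                    windowSigma = 12, excludeEdges = TRUE, seeds = NULL) {
  rule <- match.arg(rule)
  vol <- if (is(tomogram, "Tomogram")) tomogram@data else tomogram
  vs <- if (is(tomogram, "Tomogram")) tomogram@voxelSize else 1
  if (any(!is.finite(vol))) stop("tomogram must be finite")
  sm <- if (smoothSigma > 0) .gaussianBlur3(vol, smoothSigma) else vol
  weights <- NULL
  zmap <- NULL
  if (is.null(threshold) && rule == "inclusions") {
    M <- sm > .otsu(sm)
    Me <- .gaussianBlur3(M + 0, 2) > 0.97
    bp <- sm - .gaussianBlur3(sm, backgroundSigma)
    # local statistics on the signal clipped at 3 robust sigma, so that
    # large inclusions do not inflate their own background estimate
    cap <- 3 * mad(bp[Me])
    bc <- pmin(pmax(bp, -cap), cap)
    mu <- .gaussianBlur3(bc, windowSigma)
    s2 <- pmax(.gaussianBlur3(bc^2, windowSigma) - mu^2, 1e-300)
    z <- (bp - mu) / sqrt(s2)
    z[!Me] <- 0
    mask <- z > k
    weights <- pmax(bp, 0)
    zmap <- z
  } else {
    if (is.null(threshold)) {
      threshold <- switch(rule,
        otsu = .otsu(sm),
        robust = median(sm) + k * mad(sm))
    }
    mask <- sm > threshold
  }
  d <- dim(vol)
  if (!any(mask)) {
    warning("empty foreground: no voxel above the threshold")
    return(new("LabelVolume", labels = array(0L, d),
               table = .regionTable(array(0L, d)), voxelSize = vs))
  }
  if (!is.null(seeds)) {
    g <- .gradientMagnitude(sm)
    lab <- cpp_watershed3d(g, as.integer(seeds), mask, d[1], d[2], d[3])
  } else {
    lab <- cpp_label3d(mask, d[1], d[2], d[3])
  }
  tab <- .regionTable(lab, weights)
  drop <- tab$label[tab$voxels < minSize | tab$voxels > maxSize]
  if (!is.null(zmap) && nrow(tab) > 0) {
    # hysteresis: a genuine inclusion must peak well above the detection
    # threshold somewhere, not just hover at it
    peaks <- vapply(tab$label, function(lv) max(zmap[lab == lv]), numeric(1))
    drop <- union(drop, tab$label[peaks < kPeak])
  }
  if (excludeEdges && nrow(tab) > 0) {
    border <- array(FALSE, d)
    border[c(1, d[1]), , ] <- TRUE
    border[, c(1, d[2]), ] <- TRUE
    border[, , c(1, d[3])] <- TRUE
    touching <- unique(lab[border & lab > 0L])
    drop <- union(drop, touching)
  }
  if (length(drop) > 0) {
    lab[lab %in% drop] <- 0L
    tab <- tab[!(tab$label %in% drop), , drop = FALSE]
  }
  # relabel compactly in decreasing size order
  if (nrow(tab) > 0) {
    ord <- order(-tab$voxels)
    remap <- integer(max(tab$label))
    remap[tab$label[ord]] <- seq_along(ord)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
    tab <- tab[ord, , drop = FALSE]
    tab$label <- seq_along(ord)
    rownames(tab) <- NULL
  }
  new("LabelVolume", labels = array(as.integer(lab), d), table = tab,
      voxelSize = vs)
}

## central-difference gradient magnitude of a 3D array
.gradientMagnitude <- function(x) {
  d <- dim(x)
  shift <- function(arr, axis, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- d[axis]
    sel <- pmin(pmax(seq_len(n) + by, 1L), n)
    idx[[axis]] <- sel
    do.call(`[`, c(list(arr), idx))
  }
  gx <- (shift(x, 1, 1L) - shift(x, 1, -1L)) / 2
  gy <- (shift(x, 2, 1L) - shift(x, 2, -1L)) / 2
  gz <- (shift(x, 3, 1L) - shift(x, 3, -1L)) / 2
  sqrt(gx^2 + gy^2 + gz^2)
}
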