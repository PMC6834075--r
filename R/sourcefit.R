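#' @include holosim.R
NULL

#' Default fiber and geometry descriptions for coherence measurements
#'
#' The standard coherence test: a 100 um boron fiber with a 15 um tungsten
#' core, imaged at 12.7 keV with the camera 5 m downstream, 0.6 um pixels,
#' source at 61 m. Divergence is non-negligible at z = 5 m, so the simulator
#' uses the effective distance z_eff = z L / (L + z).
#'
#' @return a list with elements \code{fiber} and \code{geometry} suitable for
#'   \code{\link{modelProfile}} and \code{\link{fitSourceSize}}
#' @export
fiberGeometryDefaults <- function() {
  list(fiber = list(diameter = 100e-6, coreDiameter = 15e-6,
                    material = "boron", coreMaterial = "tungsten"),
       geometry = list(z = 5, energyKeV = 12.7, pitch = 0.6e-6,
                       n = 2048L, distance = 61, divergence = TRUE))
}

.effectiveZ <- function(geometry) {
  if (isTRUE(geometry$divergence))
    geometry$z * geometry$distance / (geometry$distance + geometry$z)
  else geometry$z
}

## noiseless propagated 1D fiber intensity before source blur (n x 1 matrix)
.fiberIntensity <- function(fiber, geometry) {
  maps <- makeFiberPhantom(fiber$diameter, fiber$coreDiameter,
                           pixel = geometry$pitch,
                           field = c(geometry$n, 1L),
                           material = fiber$material,
                           coreMaterial = fiber$coreMaterial)
  field <- propagate(transmit(maps, geometry$energyKeV), .effectiveZ(geometry))
  Mod(field@data)^2
}

#' Simulate a fiber hologram
#'
#' Full forward model of the coherence test image: analytic fiber thickness,
#' projection-approximation transmission, Fresnel propagation (with
#' divergence correction), Gaussian source blur of FWHM dEff * z_eff / L, and
#' Poisson recording. The fiber axis is horizontal, so the field is constant
#' along image columns and is propagated in 1D before replication.
#'
#' @param dEff effective source FWHM (m)
#' @param fiber,geometry as in \code{\link{fiberGeometryDefaults}}
#' @param nColumns number of image columns to replicate
#' @param fluxDensity photons / s / mm^2
#' @param exposure exposure time (s)
#' @param flat optional \linkS4class{FlatField}
#' @param seed RNG seed (NULL = noiseless expectation)
#' @return a \linkS4class{Hologram}
#' @export
simulateFiberHologram <- function(dEff = 35e-6,
                                  fiber = fiberGeometryDefaults()$fiber,
                                  geometry = fiberGeometryDefaults()$geometry,
                                  nColumns = 32L, fluxDensity = 1e13,
                                  exposure = 0.017, flat = NULL,
                                  seed = NULL) {
  intens <- .fiberIntensity(fiber, geometry)
  zEff <- .effectiveZ(geometry)
  blurred <- applyPartialCoherence(intens, geometry$pitch, zEff,
                                   dEffV = dEff, dEffH = 0,
                                   distance = geometry$distance)
  img <- matrix(rep(blurred[, 1], nColumns), nrow(blurred), nColumns)
  record(img, flat = flat, fluxDensity = fluxDensity, exposure = exposure,
         energyKeV = geometry$energyKeV, pitch = geometry$pitch,
         z = geometry$z, seed = seed)
}

#' Extract a fringe profile from a hologram
#'
#' Averages over image columns (for a horizontal fiber axis; rows for a
#' vertical one) to reduce counting noise by about sqrt(nColumns), as done
#' when analysing fiber interference patterns.
#'
#' @param hologram a \linkS4class{Hologram} (ideally flat-corrected)
#' @param orientation fiber-axis orientation: profiles run perpendicular
#' @param nColumns how many columns (rows) to average
#' @return a \linkS4class{FringeProfile}; intensities are normalized to a
#'   unit far-field mean
#' @export
extractProfile <- function(hologram, orientation = c("horizontal",
                                                     "vertical"),
                           nColumns = 10L) {
  stopifnot(is(hologram, "Hologram"))
  orientation <- match.arg(orientation)
  img <- hologram@data
  if (orientation == "vertical") img <- t(img)
  if (nColumns > ncol(img))
    stop(sprintf("nColumns = %d exceeds the %d available columns",
                 nColumns, ncol(img)))
  mid <- ncol(img) / 2
  cols <- seq(max(1L, floor(mid - nColumns / 2 + 1L)), length.out = nColumns)
  prof <- rowMeans(img[, cols, drop = FALSE])
  # normalize to the unobstructed far field (outer 15% of rows), not the
  # global mean, which the fiber shadow would bias
  nb <- max(1L, round(0.15 * length(prof)))
  scale <- median(c(head(prof, nb), tail(prof, nb)))
  if (scale > 0) prof <- prof / scale
  n <- length(prof)
  pos <- ((seq_len(n) - 0.5) - n / 2) * hologram@pitch
  new("FringeProfile", positions = pos, intensities = prof,
      pitch = hologram@pitch)
}

#' Model fringe profile for a candidate effective source size
#'
#' Noiseless 1D forward simulation (fiber -> transmit -> propagate -> source
#' blur), normalized to unit far-field intensity.
#'
#' @param dEff candidate effective source FWHM (m)
#' @param fiber,geometry as in \code{\link{fiberGeometryDefaults}}
#' @return a \linkS4class{FringeProfile}
#' @export
modelProfile <- function(dEff, fiber = fiberGeometryDefaults()$fiber,
                         geometry = fiberGeometryDefaults()$geometry) {
  holo <- simulateFiberHologram(dEff, fiber, geometry, nColumns = 1L,
                                fluxDensity = 1, exposure = 1, seed = NULL)
  extractProfile(holo, nColumns = 1L)
}

## closed-form amplitude/offset fit + residual of model m against target y
.lsResidual <- function(m, y) {
  X <- cbind(m, 1)
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

## register model to target by circular cross-correlation with parabolic
## sub-sample refinement; returns the shifted model (Fourier shift)
.registerProfile <- function(m, y) {
  mc <- m - mean(m); yc <- y - mean(y)
  cc <- .circCorr(yc, mc)
  i0 <- which.max(cc)
  ip <- .parabolicPeak(cc, i0)
  lag <- ip - 1
  n <- length(m)
  if (lag > n / 2) lag <- lag - n
  ph <- exp(-2i * pi * .fftFreq(n) * lag)
  Re(stats::fft(stats::fft(m) * ph, inverse = TRUE)) / n
}

#' Fit the effective source size to an observed fringe profile
#'
#' Forward-model fit: for each candidate d_eff the noiseless model profile is
#' registered to the observation (integer cross-correlation lag with
#' parabolic sub-pixel refinement), amplitude and offset are solved in closed
#' form, and the sum of squared differences is minimized over d_eff by a
#' coarse grid followed by golden-section refinement. The quoted uncertainty
#' is the half-width of the d_eff region whose residual stays within a
#' factor (1 + 1/n) of the minimum, a heuristic analogous to a one-sigma
#' chi-square band.
#'
#' @param observed a \linkS4class{FringeProfile} (same pitch as the model)
#' @param fiber,geometry as in \code{\link{fiberGeometryDefaults}}
#' @param searchRange candidate d_eff range (m)
#' @param coarseStep coarse grid step (m)
#' @param tol golden-section refinement tolerance (m)
#' @return a \linkS4class{SourceFitResult}; \code{boundary} is TRUE (with a
#'   warning) when the minimum sits on the search-range edge
#' @export
fitSourceSize <- function(observed, fiber = fiberGeometryDefaults()$fiber,
                          geometry = fiberGeometryDefaults()$geometry,
                          searchRange = c(5e-6, 100e-6),
                          coarseStep = 2.5e-6, tol = 0.1e-6) {
  stopifnot(is(observed, "FringeProfile"))
  if (abs(observed@pitch - geometry$pitch) > 1e-9 * geometry$pitch)
    stop("observed profile pitch must match the model geometry pitch")
  y <- observed@intensities
  n <- length(y)
  if (n != geometry$n) geometry$n <- n
  base <- .fiberIntensity(fiber, geometry)[, 1]
  base <- base / mean(base)
  zEff <- .effectiveZ(geometry)
  blurOf <- function(dEff) {
    b <- applyPartialCoherence(matrix(base, n, 1), geometry$pitch, zEff,
                               dEffV = dEff, dEffH = 0,
                               distance = geometry$distance)[, 1]
    .registerProfile(b, y)
  }
  evals <- new.env()
  evals$d <- numeric(0); evals$r <- numeric(0)
  residFor <- function(dEff) {
    r <- .lsResidual(blurOf(dEff), y)
    evals$d <- c(evals$d, dEff); evals$r <- c(evals$r, r)
    r
  }
  grid <- seq(searchRange[1], searchRange[2], by = coarseStep)
  rGrid <- vapply(grid, residFor, numeric(1))
  i <- which.min(rGrid)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  # golden-section refinement
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- residFor(x1); f2 <- residFor(x2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- residFor(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- residFor(x2)
    }
  }
  best <- which.min(evals$r)
  dBest <- evals$d[best]; rBest <- evals$r[best]
  boundary <- dBest <= searchRange[1] + tol || dBest >= searchRange[2] - tol
  if (boundary)
    warning("source-size fit minimum lies on the search-range boundary")
  thr <- rBest * (1 + 1 / n)
  within <- evals$d[evals$r <= thr]
  unc <- max(diff(range(within)) / 2, tol)
  trace <- data.frame(dEff = evals$d, residual = evals$r)
  trace <- trace[order(trace$dEff), ]
  new("SourceFitResult", dEff = dBest, uncertainty = unc, residual = rBest,
      trace = trace, boundary = boundary)
}
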