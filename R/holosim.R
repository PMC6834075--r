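#' @include phantom.R optics.R
NULL

#' Projection-approximation transmission through thickness maps
#'
#' Thin-object (projection) approximation: each material contributes
#' attenuation exp(-mu t / 2) to the amplitude and -2 pi delta t / lambda to
#' the phase. Vacuum pixels transmit a unit field.
#'
#' @param maps a \linkS4class{ThicknessMaps}
#' @param energyKeV photon energy (keV)
#' @return a \linkS4class{ComplexField} in the object exit plane
#' @export
transmit <- function(maps, energyKeV) {
  stopifnot(is(maps, "ThicknessMaps"))
  lambda <- wavelengthFromEnergy(energyKeV)
  d <- dim(maps@maps[[1]])
  muT <- matrix(0, d[1], d[2])
  deltaT <- matrix(0, d[1], d[2])
  for (m in names(maps@maps)) {
    oc <- opticalConstants(m, energyKeV)
    muT <- muT + oc@mu * maps@maps[[m]]
    deltaT <- deltaT + oc@delta * maps@maps[[m]]
  }
  field <- exp(-muT / 2) * exp(-2i * pi * deltaT / lambda)
  new("ComplexField", data = field, pitch = maps@pitch, wavelength = lambda)
}

#' Fresnel free-space propagation
#'
#' Transfer-function (angular-spectrum, paraxial) propagation: the field
#' spectrum is multiplied by H(f) = exp(-i pi lambda z |f|^2), with spatial
#' frequencies in cycles per metre. |H| = 1, so the total intensity is
#' conserved. Sampling must satisfy lambda z / pitch <= field extent in each
#' non-trivial dimension, otherwise the quadratic phase aliases.
#'
#' @param field a \linkS4class{ComplexField}
#' @param z propagation distance (m); 0 returns the field unchanged
#' @return the propagated \linkS4class{ComplexField}
#' @export
propagate <- function(field, z) {
  stopifnot(is(field, "ComplexField"))
  if (z == 0) return(field)
  d <- dim(field@data)
  pitch <- field@pitch
  need <- field@wavelength * abs(z) / pitch
  for (axis in 1:2) {
    if (d[axis] > 1L && need > d[axis] * pitch)
      stop(sprintf(
        "Fresnel sampling violated: lambda*z/pitch = %.4g m exceeds extent %.4g m (axis %d, %d px at %.3g um)",
        need, d[axis] * pitch, axis, d[axis], pitch * 1e6))
  }
  fr <- if (d[1] > 1L) .fftFreq(d[1], pitch) else 0
  fc <- if (d[2] > 1L) .fftFreq(d[2], pitch) else 0
  f2 <- outer(fr^2, fc^2, `+`)
  H <- exp(-1i * pi * field@wavelength * z * f2)
  out <- .ifft2(.fft2(field@data) * H)
  new("ComplexField", data = out, pitch = pitch,
      wavelength = field@wavelength)
}

#' Partial-coherence blur of a detector-plane intensity
#'
#' For an extended incoherent source of effective FWHM d_eff at distance L,
#' shadow geometry blurs the intensity recorded at propagation distance z by
#' a Gaussian of FWHM d_eff * z / L (per direction: vertical FWHM from the
#' vertical effective source size, horizontal from the horizontal one). The
#' mean intensity is preserved.
#'
#' @param intensity 2D intensity matrix (rows = vertical)
#' @param pitch pixel pitch (m)
#' @param z propagation distance (m)
#' @param source a \linkS4class{SourceModel}; its effective source sizes are
#'   computed with \code{\link{effectiveSourceSize}} (or give dEffV/dEffH)
#' @param dEffV vertical effective source FWHM (m), overrides \code{source}
#' @param dEffH horizontal effective source FWHM (m; default dEffV)
#' @param distance source-to-sample distance (m) when dEffV is given directly
#' @return blurred intensity matrix
#' @export
applyPartialCoherence <- function(intensity, pitch, z, source = NULL,
                                  dEffV = NULL, dEffH = dEffV,
                                  distance = if (!is.null(source))
                                    source@distance else NULL) {
  stopifnot(z >= 0)
  if (is.null(dEffV)) {
    stopifnot(is(source, "SourceModel"))
    dEffV <- effectiveSourceSize(source@fwhmV, source@dcmSpread,
                                 source@dcmDistance)
    dEffH <- effectiveSourceSize(source@fwhmH, source@dcmSpread,
                                 source@dcmDistance)
  }
  if (is.null(distance)) stop("source-to-sample distance required")
  if (z == 0 || (dEffV == 0 && dEffH == 0)) return(intensity)
  fwhmPx <- c(dEffV, dEffH) * z / distance / pitch
  sigma <- fwhmPx / (2 * sqrt(2 * log(2)))
  .gaussianBlurFFT(intensity, sigma)
}

#' Record a hologram on a photon-counting detector
#'
#' Expected counts are intensity x flat gain x flux density x pixel area x
#' exposure. With a seed, counts are drawn from a Poisson law; without, the
#' noiseless expectation is returned.
#'
#' @param intensity non-negative relative intensity (transmission) matrix
#' @param flat a \linkS4class{FlatField} or NULL (unit gain)
#' @param fluxDensity incident flux density (photons / s / mm^2)
#' @param exposure exposure time (s)
#' @param energyKeV photon energy (keV)
#' @param pitch pixel pitch (m)
#' @param z propagation distance used, stored as metadata (m)
#' @param seed RNG seed for the Poisson draw, or NULL for the expectation
#' @return a \linkS4class{Hologram} in counts
#' @export
record <- function(intensity, flat = NULL, fluxDensity, exposure, energyKeV,
                   pitch, z = 0, seed = NULL) {
  if (any(intensity < 0)) stop("intensity must be non-negative")
  if (fluxDensity < 0 || exposure < 0) stop("non-negative inputs required")
  gain <- if (is.null(flat)) 1 else flat@data
  pixAreaMm2 <- (pitch * 1e3)^2
  expected <- intensity * gain * fluxDensity * pixAreaMm2 * exposure
  data <- if (is.null(seed)) expected else
    .withSeed(seed, matrix(rpois(length(expected), expected),
                           nrow(expected), ncol(expected)))
  new("Hologram", data = data + 0.0, pitch = pitch, z = z,
      energy = energyKeV, fluxDensity = fluxDensity, exposure = exposure,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Simulate a full tomographic projection series
#'
#' For each rotation angle the chain projectThickness -> transmit ->
#' propagate -> applyPartialCoherence -> record is run, each projection being
#' recorded through one of the flat fields in the pool (as on a real
#' beamline, where the illumination fluctuates between frames). A matching
#' set of recorded flat-field images (sample out) is returned for the
#' flat-correction stage.
#'
#' Defaults are the unfocused 12.7 keV imaging configuration: z = 110 mm,
#' flux density 1e13 photons/s/mm^2, 17 ms exposure, 180 x 1 degree.
#'
#' @param phantom a \linkS4class{VoxelPhantom}
#' @param source a \linkS4class{SourceModel}
#' @param z sample-to-camera distance (m)
#' @param energyKeV photon energy (keV)
#' @param fluxDensity photons / s / mm^2
#' @param exposure exposure per projection (s)
#' @param nAngles number of projections
#' @param step angular step (degrees)
#' @param angleOffset global angular offset (degrees). NA emulates an
#'   unregistered absolute angle: a uniform random offset is drawn (seeded)
#'   and the stack is flagged \code{offsetKnown = FALSE}.
#' @param flats list of \linkS4class{FlatField}, or NULL to generate 30
#' @param nFlats pool size when generating flats
#' @param seed RNG seed; NULL gives the noiseless expectation chain
#' @return list with elements \code{stack} (\linkS4class{ProjectionStack} of
#'   counts), \code{flatImages} (recorded sample-out \linkS4class{Hologram}s),
#'   \code{flats} (the true gain patterns), \code{flatIndex} (which flat each
#'   projection saw) and \code{angleOffset}
#' @export
simulateTomoSeries <- function(phantom, source = SourceModel(), z = 0.11,
                               energyKeV = 12.7, fluxDensity = 1e13,
                               exposure = 0.017, nAngles = 180L, step = 1,
                               angleOffset = 0, flats = NULL, nFlats = 30L,
                               seed = NULL) {
  stopifnot(is(phantom, "VoxelPhantom"), nAngles >= 1L)
  d <- dim(phantom@labels)
  pitch <- phantom@voxelSize
  if (is.null(flats))
    flats <- makeFlatFields(nFlats, field = c(d[3], d[1]), pitch = pitch,
                            seed = if (is.null(seed)) 7L else
                              (as.integer(seed) + 7L) %% 2147483647L)
  offsetKnown <- TRUE
  if (is.na(angleOffset)) {
    offsetKnown <- FALSE
    angleOffset <- .withSeed(if (is.null(seed)) 11L else
      (as.integer(seed) + 11L) %% 2147483647L, runif(1, 0, 180))
  }
  relAngles <- step * (seq_len(nAngles) - 1L)
  flatIndex <- if (is.null(seed)) rep_len(seq_along(flats), nAngles) else
    .withSeed((as.integer(seed) + 13L) %% 2147483647L,
              sample.int(length(flats), nAngles, replace = TRUE))
  frames <- array(0, c(d[3], d[1], nAngles))
  mv <- .materialVolume(phantom)
  for (a in seq_len(nAngles)) {
    maps <- .projectMaterialVolume(mv, angleOffset + relAngles[a], pitch)
    field <- propagate(transmit(maps, energyKeV), z)
    intens <- applyPartialCoherence(Mod(field@data)^2, pitch, z,
                                    source = source)
    holo <- record(intens, flats[[flatIndex[a]]], fluxDensity, exposure,
                   energyKeV, pitch, z,
                   seed = if (is.null(seed)) NULL else
                     (as.integer(seed) + a) %% 2147483647L)
    frames[, , a] <- holo@data
  }
  flatImages <- lapply(seq_along(flats), function(j)
    record(matrix(1, d[3], d[1]), flats[[j]], fluxDensity, exposure,
           energyKeV, pitch, z,
           seed = if (is.null(seed)) NULL else
             (as.integer(seed) + nAngles + j) %% 2147483647L))
  stack <- new("ProjectionStack", frames = frames, angles = relAngles,
               offsetKnown = offsetKnown, pitch = pitch, z = z,
               energy = energyKeV)
  list(stack = stack, flatImages = flatImages, flats = flats,
       flatIndex = flatIndex, angleOffset = angleOffset)
}
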