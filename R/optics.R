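#' @include materials.R
NULL

#' Photon energy to wavelength
#'
#' lambda[Angstrom] = 12.3984 / E[keV], returned in metres.
#'
#' @param energyKeV photon energy in keV (> 0)
#' @return wavelength in metres
#' @examples
#' wavelengthFromEnergy(12.398) * 1e10   # 1 Angstrom
#' @export
wavelengthFromEnergy <- function(energyKeV) {
  if (!is.numeric(energyKeV) || any(!is.finite(energyKeV)) ||
      any(energyKeV <= 0))
    stop("energyKeV must be positive and finite")
  (.HC_KEV_ANGSTROM / energyKeV) * 1e-10
}

#' Transverse coherence length
#'
#' l_c = lambda * L / d for a source of FWHM d observed at distance L. The
#' prefactor-free form reproduces the coherence figures quoted for
#' synchrotron beamlines (e.g. 170 um for a 35 um source at 61 m, 12.7 keV).
#'
#' @param beam a \linkS4class{Beam}
#' @param distance source-to-observer distance L (m)
#' @param sourceFwhm source intensity-profile FWHM d (m)
#' @return transverse coherence length (m)
#' @examples
#' coherenceLength(Beam(12.7), 61, 35e-6) * 1e6   # ~170 um
#' @export
coherenceLength <- function(beam, distance, sourceFwhm) {
  stopifnot(is(beam, "Beam"))
  if (distance <= 0 || sourceFwhm <= 0)
    stop("distance and sourceFwhm must be positive")
  beam@wavelength * distance / sourceFwhm
}

#' Maximum source size for a target resolution
#'
#' Essentially coherent phase-contrast behaviour requires the transverse
#' coherence length to exceed the target resolution by about a factor of 15;
#' inverting l_c = lambda L / d gives the largest admissible source size
#' d_max = lambda * L / (coherenceFactor * resolution).
#'
#' @param resolution target imaging resolution (m)
#' @param beam a \linkS4class{Beam}
#' @param distance source-to-sample distance (m)
#' @param coherenceFactor required ratio l_c / resolution (default 15)
#' @return maximum source FWHM (m)
#' @examples
#' maxSourceSize(1e-6, Beam(12.398), 60) * 1e6   # 400 um at lambda = 1 A
#' @export
maxSourceSize <- function(resolution, beam, distance, coherenceFactor = 15) {
  stopifnot(is(beam, "Beam"))
  if (resolution <= 0 || distance <= 0)
    stop("resolution and distance must be positive")
  beam@wavelength * distance / (coherenceFactor * resolution)
}

#' Effective source size after monochromator broadening
#'
#' The angular spread introduced by the double-crystal monochromator,
#' projected back to the source plane, broadens the apparent source. For
#' Gaussian profiles the FWHMs add in quadrature:
#' d_eff = sqrt(d^2 + (spread * L_dcm)^2).
#'
#' @param sourceFwhm nominal source FWHM d (m)
#' @param dcmSpread monochromator angular spread (rad)
#' @param dcmDistance source-to-monochromator distance (m)
#' @return effective source FWHM (m)
#' @examples
#' effectiveSourceSize(13e-6, 0.7e-6, 45) * 1e6   # ~34 um
#' @export
effectiveSourceSize <- function(sourceFwhm, dcmSpread, dcmDistance) {
  if (sourceFwhm < 0 || dcmSpread < 0 || dcmDistance < 0)
    stop("inputs must be >= 0")
  sqrt(sourceFwhm^2 + (dcmSpread * dcmDistance)^2)
}

#' Focal length of a compound refractive lens
#'
#' F = R / (2 N delta) for N parabolic lenses of apex radius R, with delta
#' from \code{\link{opticalConstants}}.
#'
#' @param stack a \linkS4class{CRLStack}
#' @return focal length (m)
#' @examples
#' crlFocalLength(CRLStack(20, 50e-6, "beryllium", 10))   # ~0.37 m
#' @export
crlFocalLength <- function(stack) {
  stopifnot(is(stack, "CRLStack"))
  oc <- opticalConstants(stack@material, stack@energy)
  stack@apexRadius / (2 * stack@nLenses * oc@delta)
}

#' Solve the thin-lens equation
#'
#' 1/F = 1/L1 + 1/L2. Give exactly two of the three quantities; the third is
#' returned.
#'
#' @param F focal length (m)
#' @param L1 sample-to-lens distance (m)
#' @param L2 lens-to-image distance (m)
#' @return the missing quantity (m)
#' @examples
#' thinLensSolve(L1 = 0.40, L2 = 4.56)    # F ~ 0.368 m
#' thinLensSolve(F = 0.3665, L1 = 0.40)   # L2 ~ 4.38 m
#' @export
thinLensSolve <- function(F = NULL, L1 = NULL, L2 = NULL) {
  given <- !c(is.null(F), is.null(L1), is.null(L2))
  if (sum(given) != 2L)
    stop("give exactly two of F, L1, L2")
  if (is.null(F)) {
    if (L1 <= 0 || L2 <= 0) stop("L1 and L2 must be positive")
    return(1 / (1 / L1 + 1 / L2))
  }
  if (F <= 0) stop("F must be positive")
  if (is.null(L2)) {
    if (L1 <= 0) stop("L1 must be positive")
    if (L1 <= F)
      stop(sprintf("no real image: L1 = %.4g m <= F = %.4g m", L1, F))
    return(1 / (1 / F - 1 / L1))
  }
  if (L2 <= 0) stop("L2 must be positive")
  if (L2 <= F)
    stop(sprintf("no real object: L2 = %.4g m <= F = %.4g m", L2, F))
  1 / (1 / F - 1 / L2)
}

#' Magnification and effective pixel size
#'
#' M = L2 / L1; the detector pixel referred to the sample plane shrinks to
#' detectorPixel / M.
#'
#' @param L1 sample-to-objective distance (m)
#' @param L2 objective-to-camera distance (m)
#' @param detectorPixel sample-plane pixel pitch without the objective (m)
#' @return list with elements \code{magnification} and \code{effectivePixel}
#'   (m)
#' @examples
#' magnificationAndPixel(0.40, 4.56, 0.6e-6)   # M = 11.4, ~52.6 nm
#' @export
magnificationAndPixel <- function(L1, L2, detectorPixel) {
  if (L1 <= 0 || L2 <= 0 || detectorPixel <= 0)
    stop("L1, L2 and detectorPixel must be positive")
  M <- L2 / L1
  list(magnification = M, effectivePixel = detectorPixel / M)
}

#' Effective aperture and diffraction limit of a CRL objective
#'
#' Absorption in the lens material apodizes a parabolic CRL with a Gaussian
#' transmission profile; the effective aperture used here is
#' A_eff = correction * 2 * sqrt(R / (mu N)), and the diffraction-limited
#' resolution is delta_res = 0.75 * lambda * L1 / A_eff. Different effective
#' aperture conventions in the literature differ by factors of order unity;
#' \code{correction} is the hook to switch between them.
#'
#' @param stack a \linkS4class{CRLStack}
#' @param L1 sample-to-objective distance (m)
#' @param correction dimensionless prefactor on the Gaussian effective
#'   aperture (default 1)
#' @return list with \code{effectiveAperture} (m) and \code{diffractionLimit}
#'   (m)
#' @examples
#' crlResolution(CRLStack(20, 50e-6, "beryllium", 10), L1 = 0.40)
#' @export
crlResolution <- function(stack, L1, correction = 1) {
  stopifnot(is(stack, "CRLStack"))
  if (L1 <= 0) stop("L1 must be positive")
  oc <- opticalConstants(stack@material, stack@energy)
  aEff <- correction * 2 * sqrt(stack@apexRadius / (oc@mu * stack@nLenses))
  lambda <- wavelengthFromEnergy(stack@energy)
  list(effectiveAperture = aEff,
       diffractionLimit = 0.75 * lambda * L1 / aEff)
}
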