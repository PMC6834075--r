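#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Beamline / optics value classes
## ---------------------------------------------------------------------------

#' Monochromatic X-ray beam
#'
#' Photon energy and vacuum wavelength of the (monochromatic) beam. The two
#' are locked together through E * lambda = 12.3984 keV Angstrom.
#'
#' @slot energy photon energy (keV)
#' @slot wavelength wavelength (m)
#' @export
setClass("Beam", representation(energy = "numeric", wavelength = "numeric"))

setValidity("Beam", function(object) {
  if (length(object@energy) != 1L || length(object@wavelength) != 1L)
    return("energy and wavelength must be scalars")
  if (!is.finite(object@energy) || object@energy <= 0)
    return("energy must be positive and finite")
  if (!is.finite(object@wavelength) || object@wavelength <= 0)
    return("wavelength must be positive and finite")
  prod <- object@energy * (object@wavelength * 1e10)
  if (abs(prod - .HC_KEV_ANGSTROM) > 1e-4 * .HC_KEV_ANGSTROM)
    return("energy * wavelength deviates from hc = 12.398 keV Angstrom")
  TRUE
})

#' Construct a Beam from its photon energy
#'
#' @param energyKeV photon energy in keV (> 0)
#' @return a \linkS4class{Beam}
#' @examples
#' Beam(12.7)
#' @export
Beam <- function(energyKeV) {
  new("Beam", energy = energyKeV,
      wavelength = wavelengthFromEnergy(energyKeV))
}

setMethod("photonEnergy", "Beam", function(x) x@energy)

#' Wavelength accessor for a Beam
#' @param beam a \linkS4class{Beam}
#' @return wavelength in metres
#' @export
beamWavelength <- function(beam) beam@wavelength

setMethod("show", "Beam", function(object) {
  cat(sprintf("Beam: %.4g keV (lambda = %.5g Angstrom)\n",
              object@energy, object@wavelength * 1e10))
})

#' X-ray source model
#'
#' Gaussian source intensity profile (FWHM in both directions), distance to
#' the sample and the position/angular spread of the double-crystal
#' monochromator (DCM) that broadens the effective source.
#'
#' @slot fwhmV vertical source FWHM (m)
#' @slot fwhmH horizontal source FWHM (m)
#' @slot distance source-to-sample distance L (m)
#' @slot dcmDistance source-to-monochromator distance (m)
#' @slot dcmSpread monochromator angular spread (rad)
#' @export
setClass("SourceModel",
         representation(fwhmV = "numeric", fwhmH = "numeric",
                        distance = "numeric", dcmDistance = "numeric",
                        dcmSpread = "numeric"))

setValidity("SourceModel", function(object) {
  len <- c(object@fwhmV, object@fwhmH, object@distance, object@dcmDistance)
  if (any(!is.finite(len)) || any(len <= 0))
    return("all lengths must be positive and finite")
  if (!is.finite(object@dcmSpread) || object@dcmSpread < 0)
    return("dcmSpread must be >= 0")
  TRUE
})

#' Construct a SourceModel
#'
#' Defaults describe the P14-like geometry used throughout the package:
#' nominal 13 x 330 um (V x H) source at 61 m, DCM at 45 m with 0.7 urad
#' angular spread.
#'
#' @param fwhmV vertical source FWHM (m)
#' @param fwhmH horizontal source FWHM (m)
#' @param distance source-to-sample distance (m)
#' @param dcmDistance source-to-monochromator distance (m)
#' @param dcmSpread monochromator angular spread (rad)
#' @return a \linkS4class{SourceModel}
#' @export
SourceModel <- function(fwhmV = 13e-6, fwhmH = 330e-6, distance = 61,
                        dcmDistance = 45, dcmSpread = 0.7e-6) {
  new("SourceModel", fwhmV = fwhmV, fwhmH = fwhmH, distance = distance,
      dcmDistance = dcmDistance, dcmSpread = dcmSpread)
}

setMethod("show", "SourceModel", function(object) {
  cat(sprintf(
    "SourceModel: %.3g x %.3g um FWHM (V x H) at L = %.3g m; DCM %.2g urad at %.3g m\n",
    object@fwhmV * 1e6, object@fwhmH * 1e6, object@distance,
    object@dcmSpread * 1e6, object@dcmDistance))
})

#' Optical constants of a material at one energy
#'
#' @slot material material identifier
#' @slot energy photon energy (keV)
#' @slot delta refractive index decrement (dimensionless)
#' @slot beta imaginary part of the refractive index (dimensionless)
#' @slot mu linear attenuation coefficient (1/m)
#' @slot muEnRho mass energy-absorption coefficient (m^2/kg)
#' @slot density mass density (kg/m^3)
#' @export
setClass("OpticalConstants",
         representation(material = "character", energy = "numeric",
                        delta = "numeric", beta = "numeric", mu = "numeric",
                        muEnRho = "numeric", density = "numeric"))

setValidity("OpticalConstants", function(object) {
  v <- c(object@delta, object@beta, object@mu, object@muEnRho)
  if (any(!is.finite(v)) || any(v < 0))
    return("delta, beta, mu, muEnRho must be non-negative")
  lambda <- wavelengthFromEnergy(object@energy)
  if (object@beta > 0 &&
      abs(object@mu - 4 * pi * object@beta / lambda) > 1e-3 * object@mu)
    return("mu and beta are inconsistent (mu != 4 pi beta / lambda)")
  TRUE
})

setMethod("photonEnergy", "OpticalConstants", function(x) x@energy)

setMethod("show", "OpticalConstants", function(object) {
  cat(sprintf("OpticalConstants: %s at %.4g keV\n", object@material,
              object@energy))
  cat(sprintf("  delta = %.4g, beta = %.4g\n", object@delta, object@beta))
  cat(sprintf("  mu = %.4g 1/m, mu_en/rho = %.4g m^2/kg\n",
              object@mu, object@muEnRho))
})

#' Compound refractive lens stack
#'
#' @slot nLenses number of individual parabolic lenses (>= 1)
#' @slot apexRadius apex radius of curvature R (m)
#' @slot material lens material identifier
#' @slot energy photon energy (keV)
#' @export
setClass("CRLStack",
         representation(nLenses = "integer", apexRadius = "numeric",
                        material = "character", energy = "numeric"))

setValidity("CRLStack", function(object) {
  if (object@nLenses < 1L) return("nLenses must be >= 1")
  if (!is.finite(object@apexRadius) || object@apexRadius <= 0)
    return("apexRadius must be positive")
  TRUE
})

#' Construct a CRL stack
#'
#' Defaults give the 20-lens beryllium objective with 50 um apex radius
#' operated at 10 keV.
#'
#' @param nLenses number of lenses
#' @param apexRadius apex radius (m)
#' @param material lens material
#' @param energyKeV photon energy (keV)
#' @return a \linkS4class{CRLStack}
#' @export
CRLStack <- function(nLenses = 20L, apexRadius = 50e-6,
                     material = "beryllium", energyKeV = 10) {
  new("CRLStack", nLenses = as.integer(nLenses), apexRadius = apexRadius,
      material = material, energy = energyKeV)
}

setMethod("show", "CRLStack", function(object) {
  cat(sprintf("CRLStack: %d x %s lenses, R = %.3g um, at %.4g keV\n",
              object@nLenses, object@material, object@apexRadius * 1e6,
              object@energy))
})

## ---------------------------------------------------------------------------
## Phantom containers
## ---------------------------------------------------------------------------

#' Per-material projected thickness maps
#'
#' One 2D thickness grid (metres) per material, all sharing shape and pixel
#' pitch. Row index runs along the vertical (rotation-axis) direction with
#' row 1 at the top; column index runs along the horizontal detector axis.
#'
#' @slot maps named list of numeric matrices (thickness in m)
#' @slot pitch pixel pitch (m)
#' @slot angle projection angle (degrees)
#' @export
setClass("ThicknessMaps",
         representation(maps = "list", pitch = "numeric", angle = "numeric"))

setValidity("ThicknessMaps", function(object) {
  if (length(object@maps) == 0L) return("at least one material map required")
  if (is.null(names(object@maps)) || any(names(object@maps) == ""))
    return("maps must be named by material")
  dims <- lapply(object@maps, dim)
  if (length(unique(dims)) != 1L) return("all maps must share one shape")
  if (any(vapply(object@maps, function(m) any(m < 0) || any(!is.finite(m)),
                 logical(1))))
    return("thickness must be finite and non-negative everywhere")
  if (object@pitch <= 0) return("pitch must be positive")
  TRUE
})

setMethod("pixelPitch", "ThicknessMaps", function(x) x@pitch)

setMethod("show", "ThicknessMaps", function(object) {
  d <- dim(object@maps[[1]])
  cat(sprintf("ThicknessMaps: %d x %d px at %.3g um, angle %.4g deg\n",
              d[1], d[2], object@pitch * 1e6, object@angle))
  cat("  materials:", paste(names(object@maps), collapse = ", "), "\n")
})

#' Labeled voxel phantom
#'
#' Integer label volume with a label-to-material map and the generator's
#' ground truth (per-crystal centroids and volumes). Axis 3 is the vertical
#' rotation axis.
#'
#' @slot labels 3D integer array of region labels
#' @slot voxelSize voxel edge (m)
#' @slot materials data.frame with columns label, material, role
#' @slot groundTruth list(count, centroids, volumes)
#' @export
setClass("VoxelPhantom",
         representation(labels = "array", voxelSize = "numeric",
                        materials = "data.frame", groundTruth = "list"))

setValidity("VoxelPhantom", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be 3D")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  used <- sort(unique(as.integer(object@labels)))
  used <- used[used != 0L]
  if (!all(used %in% object@materials$label))
    return("every non-zero label must be mapped to a material")
  gt <- object@groundTruth
  if (!all(c("count", "centroids", "volumes") %in% names(gt)))
    return("groundTruth must have count, centroids, volumes")
  if (gt$count != nrow(gt$centroids) || gt$count != length(gt$volumes))
    return("groundTruth count inconsistent with centroids/volumes")
  TRUE
})

setMethod("voxelSize", "VoxelPhantom", function(x) x@voxelSize)
setMethod("groundTruth", "VoxelPhantom", function(x) x@groundTruth)
setMethod("imageData", "VoxelPhantom", function(x) x@labels)

setMethod("show", "VoxelPhantom", function(object) {
  d <- dim(object@labels)
  cat(sprintf("VoxelPhantom: %d x %d x %d voxels at %.3g um\n",
              d[1], d[2], d[3], object@voxelSize * 1e6))
  cat(sprintf("  %d crystals; materials: %s\n", object@groundTruth$count,
              paste(unique(object@materials$material), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## Wave / detector containers
## ---------------------------------------------------------------------------

#' Complex scalar wave field
#'
#' @slot data complex matrix of the field amplitude
#' @slot pitch transverse sampling pitch (m)
#' @slot wavelength wavelength (m)
#' @export
setClass("ComplexField",
         representation(data = "matrix", pitch = "numeric",
                        wavelength = "numeric"))

setValidity("ComplexField", function(object) {
  if (!is.complex(object@data)) return("data must be complex")
  if (any(!is.finite(Mod(object@data)))) return("field values must be finite")
  if (object@pitch <= 0 || object@wavelength <= 0)
    return("pitch and wavelength must be positive")
  TRUE
})

setMethod("imageData", "ComplexField", function(x) x@data)
setMethod("pixelPitch", "ComplexField", function(x) x@pitch)

setMethod("show", "ComplexField", function(object) {
  d <- dim(object@data)
  cat(sprintf("ComplexField: %d x %d px at %.3g um, lambda = %.4g Angstrom\n",
              d[1], d[2], object@pitch * 1e6, object@wavelength * 1e10))
})

#' Detector-plane flat field
#'
#' Strictly positive pixel gain pattern (dimensionless).
#'
#' @slot data positive numeric matrix
#' @slot pitch pixel pitch (m)
#' @export
setClass("FlatField", representation(data = "matrix", pitch = "numeric"))

setValidity("FlatField", function(object) {
  if (any(!is.finite(object@data)) || any(object@data <= 0))
    return("flat field must be strictly positive and finite")
  if (object@pitch <= 0) return("pitch must be positive")
  TRUE
})

setMethod("imageData", "FlatField", function(x) x@data)
setMethod("pixelPitch", "FlatField", function(x) x@pitch)

#' In-line hologram (detector intensity image)
#'
#' @slot data non-negative intensity matrix (counts, or expected counts)
#' @slot pitch pixel pitch (m)
#' @slot z propagation (sample-to-camera) distance (m)
#' @slot energy photon energy (keV)
#' @slot fluxDensity incident flux density (photons / s / mm^2; NA if unknown)
#' @slot exposure exposure time (s; NA if unknown)
#' @slot seed RNG seed used for counting noise (NA = noiseless expectation)
#' @export
setClass("Hologram",
         representation(data = "matrix", pitch = "numeric", z = "numeric",
                        energy = "numeric", fluxDensity = "numeric",
                        exposure = "numeric", seed = "numeric"))

setValidity("Hologram", function(object) {
  if (any(!is.finite(object@data)) || any(object@data < 0))
    return("intensities must be finite and >= 0")
  if (object@pitch <= 0) return("pitch must be positive")
  if (object@z < 0) return("z must be >= 0")
  if (object@energy <= 0) return("energy must be positive")
  TRUE
})

setMethod("imageData", "Hologram", function(x) x@data)
setMethod("pixelPitch", "Hologram", function(x) x@pitch)
setMethod("photonEnergy", "Hologram", function(x) x@energy)

setMethod("show", "Hologram", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "Hologram: %d x %d px at %.3g um, z = %.4g m, %.4g keV%s\n",
    d[1], d[2], object@pitch * 1e6, object@z, object@energy,
    if (is.na(object@seed)) " (expectation)" else
      sprintf(" (Poisson, seed %d)", as.integer(object@seed))))
})

#' Ordered tomographic projection series
#'
#' @slot frames 3D numeric array (rows x cols x angles)
#' @slot angles relative rotation angles (degrees, uniform spacing)
#' @slot offsetKnown FALSE when the absolute (global) angle is unregistered
#' @slot pitch pixel pitch (m)
#' @slot z sample-to-camera distance (m)
#' @slot energy photon energy (keV)
#' @export
setClass("ProjectionStack",
         representation(frames = "array", angles = "numeric",
                        offsetKnown = "logical", pitch = "numeric",
                        z = "numeric", energy = "numeric"))

setValidity("ProjectionStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3D array")
  if (d[3] != length(object@angles))
    return("number of frames must match number of angles")
  if (length(object@angles) > 1L) {
    steps <- diff(object@angles)
    if (any(abs(steps - steps[1]) > 1e-9 * max(1, abs(steps[1]))))
      return("angles must be uniformly spaced")
  }
  TRUE
})

setMethod("imageData", "ProjectionStack", function(x) x@frames)
setMethod("pixelPitch", "ProjectionStack", function(x) x@pitch)
setMethod("photonEnergy", "ProjectionStack", function(x) x@energy)
setMethod("angles", "ProjectionStack", function(x) x@angles)

setMethod("show", "ProjectionStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "ProjectionStack: %d frames of %d x %d px, %.4g..%.4g deg, z = %.4g m\n",
    d[3], d[1], d[2], min(object@angles), max(object@angles), object@z))
})

#' Single-slice sinogram
#'
#' Rows are projection angles, columns detector positions.
#'
#' @slot data numeric matrix (angles x detector columns)
#' @slot angles rotation angles (degrees)
#' @slot center center of rotation in 0-based detector pixel units (NA if
#'   not yet determined)
#' @export
setClass("Sinogram",
         representation(data = "matrix", angles = "numeric",
                        center = "numeric"))

setValidity("Sinogram", function(object) {
  if (nrow(object@data) != length(object@angles))
    return("rows must equal the number of projection angles")
  TRUE
})

setMethod("imageData", "Sinogram", function(x) x@data)
setMethod("angles", "Sinogram", function(x) x@angles)

#' Rotation-center accessor
#' @param x a \linkS4class{Sinogram}
#' @return center of rotation (0-based pixel units) or NA
#' @export
rotationCenter <- function(x) x@center

#' Reconstructed tomogram
#'
#' Gray values are proportional to the local attenuation coefficient (no
#' absolute calibration). Axis 3 is the vertical rotation axis, matching
#' \linkS4class{VoxelPhantom}.
#'
#' @slot data 3D numeric array
#' @slot voxelSize voxel edge (m), equal to the projection pixel pitch
#' @export
setClass("Tomogram", representation(data = "array", voxelSize = "numeric"))

setValidity("Tomogram", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be 3D")
  if (any(!is.finite(object@data))) return("tomogram values must be finite")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  TRUE
})

setMethod("imageData", "Tomogram", function(x) x@data)
setMethod("voxelSize", "Tomogram", function(x) x@voxelSize)

setMethod("show", "Tomogram", function(object) {
  d <- dim(object@data)
  cat(sprintf("Tomogram: %d x %d x %d voxels at %.3g um\n",
              d[1], d[2], d[3], object@voxelSize * 1e6))
})

#' Segmented label volume
#'
#' @slot labels 3D integer array (0 = background)
#' @slot table data.frame: label, voxels, cx, cy, cz (voxel coordinates)
#' @slot voxelSize voxel edge (m)
#' @export
setClass("LabelVolume",
         representation(labels = "array", table = "data.frame",
                        voxelSize = "numeric"))

setValidity("LabelVolume", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be 3D")
  lab <- sort(unique(as.integer(object@labels)))
  lab <- lab[lab != 0L]
  if (!setequal(lab, object@table$label))
    return("region table inconsistent with label volume")
  TRUE
})

setMethod("imageData", "LabelVolume", function(x) x@labels)
setMethod("regionTable", "LabelVolume", function(x) x@table)
setMethod("voxelSize", "LabelVolume", function(x) x@voxelSize)

setMethod("show", "LabelVolume", function(object) {
  cat(sprintf("LabelVolume: %d regions in %s volume\n",
              nrow(object@table), paste(dim(object@labels), collapse = " x ")))
})

## ---------------------------------------------------------------------------
## Dose classes
## ---------------------------------------------------------------------------

#' Exposure specification
#'
#' Either a flux density, or a total flux plus beam area, together with
#' exposure time and photon energy.
#'
#' @slot fluxDensity photons / s / mm^2
#' @slot flux photons / s (NA when only a flux density is given)
#' @slot areaMm2 beam cross-section (mm^2; NA when only a flux density is given)
#' @slot time exposure time per repeat (s)
#' @slot energy photon energy (keV)
#' @slot nRepeats number of identical exposures (e.g. projections)
#' @export
setClass("ExposureSpec",
         representation(fluxDensity = "numeric", flux = "numeric",
                        areaMm2 = "numeric", time = "numeric",
                        energy = "numeric", nRepeats = "numeric"))

setValidity("ExposureSpec", function(object) {
  if (object@time < 0 || object@energy <= 0 || object@nRepeats < 0)
    return("time, nRepeats must be >= 0 and energy > 0")
  if (is.na(object@fluxDensity)) return("fluxDensity must be set")
  if (object@fluxDensity < 0) return("fluxDensity must be >= 0")
  if (!is.na(object@flux) && !is.na(object@areaMm2)) {
    implied <- object@flux / object@areaMm2
    if (implied > 0 &&
        abs(implied - object@fluxDensity) > 1e-3 * implied)
      return("fluxDensity inconsistent with flux / area")
  }
  TRUE
})

#' Construct an ExposureSpec
#'
#' @param fluxDensity photons / s / mm^2 (omit when flux and areaMm2 given)
#' @param flux total photons / s
#' @param areaMm2 beam cross-section in mm^2
#' @param time exposure time per repeat (s)
#' @param energyKeV photon energy (keV)
#' @param nRepeats number of identical exposures
#' @return an \linkS4class{ExposureSpec}
#' @examples
#' ExposureSpec(fluxDensity = 1e13, time = 0.017, energyKeV = 12.7)
#' @export
ExposureSpec <- function(fluxDensity = NULL, flux = NULL, areaMm2 = NULL,
                         time, energyKeV, nRepeats = 1) {
  if (is.null(fluxDensity)) {
    if (is.null(flux) || is.null(areaMm2))
      stop("give either fluxDensity, or flux together with areaMm2")
    fluxDensity <- flux / areaMm2
  }
  new("ExposureSpec", fluxDensity = fluxDensity,
      flux = if (is.null(flux)) NA_real_ else flux,
      areaMm2 = if (is.null(areaMm2)) NA_real_ else areaMm2,
      time = time, energy = energyKeV, nRepeats = nRepeats)
}

setMethod("photonEnergy", "ExposureSpec", function(x) x@energy)

#' Absorbed-dose result
#'
#' @slot dose absorbed dose (Gy)
#' @slot fluence photon fluence (photons / m^2)
#' @slot energyFluence energy fluence (J / m^2)
#' @slot absorber absorbing material id
#' @export
setClass("DoseResult",
         representation(dose = "numeric", fluence = "numeric",
                        energyFluence = "numeric", absorber = "character"))

setValidity("DoseResult", function(object) {
  if (object@dose < 0) return("dose must be >= 0")
  TRUE
})

setMethod("doseGray", "DoseResult", function(x) x@dose)

setMethod("show", "DoseResult", function(object) {
  cat(sprintf("DoseResult: %.4g Gy in %s (fluence %.4g ph/m^2)\n",
              object@dose, object@absorber, object@fluence))
})

## ---------------------------------------------------------------------------
## Source-fit classes
## ---------------------------------------------------------------------------

#' 1D fringe profile
#'
#' @slot positions strictly increasing, uniformly spaced positions (m),
#'   relative to the fiber axis
#' @slot intensities flat-corrected intensities (dimensionless, >= 0)
#' @slot pitch sampling pitch (m)
#' @export
setClass("FringeProfile",
         representation(positions = "numeric", intensities = "numeric",
                        pitch = "numeric"))

setValidity("FringeProfile", function(object) {
  if (length(object@positions) != length(object@intensities))
    return("positions and intensities must have equal length")
  d <- diff(object@positions)
  if (any(d <= 0) || any(abs(d - d[1]) > 1e-6 * d[1]))
    return("positions must be strictly increasing and uniform")
  if (any(object@intensities < 0)) return("intensities must be >= 0")
  TRUE
})

setMethod("show", "FringeProfile", function(object) {
  cat(sprintf("FringeProfile: %d samples at %.3g um pitch, span %.4g um\n",
              length(object@positions), object@pitch * 1e6,
              diff(range(object@positions)) * 1e6))
})

#' Effective-source-size fit result
#'
#' @slot dEff fitted effective source FWHM (m)
#' @slot uncertainty heuristic uncertainty (m)
#' @slot residual minimal sum of squared differences
#' @slot trace data.frame of evaluated candidates (dEff, residual)
#' @slot boundary TRUE when the minimum sits on the search-range boundary
#' @export
setClass("SourceFitResult",
         representation(dEff = "numeric", uncertainty = "numeric",
                        residual = "numeric", trace = "data.frame",
                        boundary = "logical"))

setValidity("SourceFitResult", function(object) {
  if (nrow(object@trace) > 0 &&
      object@residual > min(object@trace$residual) + 1e-9 * object@residual)
    return("stored residual must be minimal over the trace")
  TRUE
})

#' Fitted effective source size
#' @param x a \linkS4class{SourceFitResult}
#' @return fitted FWHM in metres
#' @export
fittedSourceSize <- function(x) x@dEff

#' Search trace of a source-size fit
#' @param x a \linkS4class{SourceFitResult}
#' @return data.frame with columns dEff and residual
#' @export
fitTrace <- function(x) x@trace

setMethod("show", "SourceFitResult", function(object) {
  cat(sprintf("SourceFitResult: d_eff = %.3g +- %.2g um (residual %.4g)%s\n",
              object@dEff * 1e6, object@uncertainty * 1e6, object@residual,
              if (object@boundary) " [boundary!]" else ""))
})
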