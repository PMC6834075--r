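#' @include phaseCT-package.R
NULL

#' Pixel or voxel data of an image-like object
#'
#' Extract the numeric array stored in a phaseCT image container:
#' intensities for \linkS4class{Hologram} and \linkS4class{FlatField},
#' complex amplitudes for \linkS4class{ComplexField}, gray values for
#' \linkS4class{Tomogram}, line integrals for \linkS4class{Sinogram},
#' integer labels for \linkS4class{LabelVolume} and the full frame array
#' for \linkS4class{ProjectionStack}.
#'
#' @param x an image-like phaseCT object
#' @return a numeric, complex or integer matrix/array
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' Pixel pitch of an image-like object
#'
#' @param x an object carrying a detector or sample-plane pixel pitch
#' @return pixel pitch in metres
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))

#' Photon energy of an object
#'
#' @param x an object carrying a photon energy
#' @return photon energy in keV
#' @export
setGeneric("photonEnergy", function(x) standardGeneric("photonEnergy"))

#' Projection angles
#'
#' @param x a \linkS4class{ProjectionStack} or \linkS4class{Sinogram}
#' @return numeric vector of relative rotation angles in degrees
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))

#' Voxel size
#'
#' @param x a \linkS4class{VoxelPhantom}, \linkS4class{Tomogram} or
#'   \linkS4class{LabelVolume}
#' @return voxel edge length in metres
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Ground truth of a synthetic phantom
#'
#' @param x a \linkS4class{VoxelPhantom}
#' @return a list with elements \code{count}, \code{centroids} (voxel
#'   coordinates, one row per crystal) and \code{volumes} (voxel counts)
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' Region table of a segmented volume
#'
#' @param x a \linkS4class{LabelVolume}
#' @return a data.frame with one row per region: label, voxel count and
#'   centroid coordinates (voxel units)
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' Absorbed dose in gray
#'
#' @param x a \linkS4class{DoseResult}
#' @return absorbed dose in Gy
#' @export
setGeneric("doseGray", function(x) standardGeneric("doseGray"))
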