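#' @include optics.R
NULL

#' Thin-sample absorbed dose from an exposure
#'
#' Kerma-style thin-sample model: the absorbed dose is the energy fluence
#' times the mass energy-absorption coefficient of the absorber,
#' D = nRepeats * fluxDensity * time * E_photon * (mu_en/rho),
#' with no depth attenuation (valid for samples much thinner than the
#' attenuation length, as for crystals and LCP layers of tens of
#' micrometres at >10 keV).
#'
#' @param spec an \linkS4class{ExposureSpec}
#' @param absorber absorbing material id (default "water")
#' @return a \linkS4class{DoseResult}
#' @examples
#' # single unfocused projection: ~80 Gy
#' doseFromExposure(ExposureSpec(fluxDensity = 1e13, time = 0.017,
#'                               energyKeV = 12.7))
#' @export
doseFromExposure <- function(spec, absorber = "water") {
  stopifnot(is(spec, "ExposureSpec"))
  validObject(spec)
  oc <- opticalConstants(absorber, spec@energy)
  fluence <- spec@nRepeats * spec@fluxDensity * 1e6 * spec@time  # ph/m^2
  eJ <- spec@energy * 1e3 * .EV_JOULE
  energyFluence <- fluence * eJ
  new("DoseResult", dose = energyFluence * oc@muEnRho, fluence = fluence,
      energyFluence = energyFluence, absorber = tolower(absorber))
}

#' Default exposure scenarios of the imaging workflow
#'
#' The four acquisition modes considered throughout the package: microfocus
#' diffraction raster scanning, single-shot full-field imaging, a 180 x 1
#' degree tomography series, and CRL microscopy with a condensed beam.
#'
#' @return named list of \linkS4class{ExposureSpec}
#' @export
beamlineExposureScenarios <- function() {
  list(
    `raster scan` = ExposureSpec(flux = 1.2e13, areaMm2 = 5e-3 * 10e-3,
                                 time = 7.5e-3, energyKeV = 12.7,
                                 nRepeats = 4998),
    `imaging (single shot)` = ExposureSpec(flux = 4e12,
                                           areaMm2 = 0.614 * 0.614,
                                           time = 0.017, energyKeV = 12.7),
    `tomography (180 projections)` = ExposureSpec(flux = 4e12,
                                                  areaMm2 = 0.614 * 0.614,
                                                  time = 0.017,
                                                  energyKeV = 12.7,
                                                  nRepeats = 180),
    `microscopy (single shot)` = ExposureSpec(flux = 1.5e12,
                                              areaMm2 = 0.054 * 0.054,
                                              time = 1, energyKeV = 10)
  )
}

#' Dose bookkeeping table for a set of exposure scenarios
#'
#' Derives the flux density (from flux / area when both are given), total
#' exposure time and thin-sample dose for each named scenario.
#'
#' For scanned acquisitions (the beam visits each sample point once) the dose
#' to the irradiated region is the single-repeat dose, not the accumulated
#' one; scenarios named in \code{scannedScenarios} are treated that way.
#' Doses for focused-beam modes (raster scan, microscopy) depend strongly on
#' the absorber composition and beam-profile handling and should be read as
#' order-of-magnitude values under the thin water-equivalent model.
#'
#' @param specs named list of \linkS4class{ExposureSpec} (default:
#'   \code{\link{beamlineExposureScenarios}()})
#' @param absorber absorbing material id
#' @param scannedScenarios names of scenarios where repeats illuminate
#'   different sample regions
#' @return data.frame with columns scenario, energy_keV,
#'   flux_density_ph_s_mm2, total_exposure_s, dose_kGy
#' @examples
#' doseReport()
#' @export
doseReport <- function(specs = beamlineExposureScenarios(),
                       absorber = "water",
                       scannedScenarios = "raster scan") {
  stopifnot(length(specs) >= 1, !is.null(names(specs)))
  rows <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    d <- doseFromExposure(sp, absorber)
    dose <- if (nm %in% scannedScenarios) d@dose / sp@nRepeats else d@dose
    data.frame(scenario = nm,
               energy_keV = sp@energy,
               flux_density_ph_s_mm2 = sp@fluxDensity,
               total_exposure_s = sp@time * sp@nRepeats,
               dose_kGy = dose / 1e3,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
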