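#' @include AllClasses.R
NULL

## Compact X-ray constants, 5-30 keV.
##
## Per-element mass attenuation (mu/rho) and mass energy-absorption
## (mu_en/rho) coefficients in cm^2/g on a coarse log energy grid, assembled
## from the standard NIST compilations (Hubbell & Seltzer) with power-law
## completion between tabulated anchors. Compounds are combined by mass
## fraction. Log-log interpolation in energy. W and Ta start above their L1
## edges (12.5 keV): a coarse log grid cannot represent the 10.2-12.1 keV
## edge structure, so lookups below that are refused rather than wrong.
##
## The refractive index decrement delta is not tabulated: away from
## absorption edges it follows from the electron density alone,
##   delta = r_e lambda^2 n_e / (2 pi),
## and beta is tied to the attenuation table through mu = 4 pi beta / lambda.

.ELEMENTS <- list(
  H = list(ZA = 0.99212,
           E = c(5, 8, 10, 15, 20, 30),
           mu = c(0.4116, 0.3914, 0.3854, 0.3764, 0.3695, 0.3570),
           muen = c(0.01200, 0.01000, 0.00986, 0.01102, 0.01331, 0.01668)),
  C = list(ZA = 0.49954,
           E = c(5, 8, 10, 15, 20, 30),
           mu = c(18.95, 4.576, 2.373, 0.8071, 0.4420, 0.2562),
           muen = c(18.48, 4.242, 2.078, 0.5627, 0.2238, 0.06614)),
  N = list(ZA = 0.49976,
           E = c(5, 8, 10, 15, 20, 30),
           mu = c(31.30, 7.410, 3.879, 1.236, 0.6178, 0.2933),
           muen = c(30.50, 6.950, 3.545, 0.9640, 0.3830, 0.1061)),
  O = list(ZA = 0.50002,
           E = c(5, 8, 10, 15, 20, 30),
           mu = c(47.30, 11.63, 5.952, 1.836, 0.8651, 0.3779),
           muen = c(46.72, 11.16, 5.565, 1.5458, 0.6180, 0.1732)),
  S = list(ZA = 0.49897,
           E = c(5, 8, 10, 15, 20, 30),
           mu = c(350.0, 95.60, 50.33, 15.90, 6.900, 2.113),
           muen = c(335.0, 91.00, 47.80, 14.80, 6.200, 1.800)),
  Be = list(ZA = 0.44384,
            E = c(5, 8, 10, 15, 20, 30),
            mu = c(4.000, 1.118, 0.6466, 0.3075, 0.2245, 0.1755),
            muen = c(3.800, 1.000, 0.4890, 0.1500, 0.0750, 0.0320)),
  B = list(ZA = 0.46249,
           E = c(5, 8, 10, 15, 20, 30),
           mu = c(9.490, 2.350, 1.255, 0.4713, 0.2845, 0.1854),
           muen = c(9.200, 2.200, 1.100, 0.3300, 0.1500, 0.0600)),
  W = list(ZA = 0.40252,
           E = c(12.5, 15, 20, 30),
           mu = c(228.0, 139.3, 65.73, 22.73),
           muen = c(170.0, 103.0, 48.70, 17.20)),
  Ta = list(ZA = 0.40342,
            E = c(12.5, 15, 20, 30),
            mu = c(221.0, 134.0, 63.00, 21.80),
            muen = c(165.0, 100.0, 47.00, 16.50))
)

## density in g/cm^3; composition = named mass fractions
.MATERIALS <- list(
  water     = list(density = 1.000,
                   composition = c(H = 0.1119, O = 0.8881)),
  beryllium = list(density = 1.848, composition = c(Be = 1)),
  boron     = list(density = 2.340, composition = c(B = 1)),
  tungsten  = list(density = 19.30, composition = c(W = 1)),
  tantalum  = list(density = 16.654, composition = c(Ta = 1)),
  ## average protein composition, dry crystal density
  protein   = list(density = 1.350,
                   composition = c(H = 0.070, C = 0.530, N = 0.160,
                                   O = 0.227, S = 0.013)),
  ## lipidic cubic phase approximated as 60% monoolein (C21H40O4) + 40% water
  lcp       = list(density = 0.990,
                   composition = c(H = 0.1126, C = 0.4245, O = 0.4629)),
  kapton    = list(density = 1.420,
                   composition = c(H = 0.0264, C = 0.6911, N = 0.0733,
                                   O = 0.2092))
)
.MATERIALS$lipid <- .MATERIALS$lcp

#' Supported material identifiers
#'
#' @return character vector of material ids accepted by
#'   \code{\link{opticalConstants}}
#' @export
supportedMaterials <- function() names(.MATERIALS)

## log-log interpolation of one element table; refuses extrapolation
.elementCoef <- function(symbol, energyKeV, what = c("mu", "muen")) {
  what <- match.arg(what)
  el <- .ELEMENTS[[symbol]]
  if (energyKeV < min(el$E) || energyKeV > max(el$E))
    stop(sprintf(
      "energy %.4g keV outside the %s table span [%.4g, %.4g] keV",
      energyKeV, symbol, min(el$E), max(el$E)))
  exp(approx(log(el$E), log(el[[what]]), xout = log(energyKeV))$y)
}

.materialSpec <- function(material) {
  m <- .MATERIALS[[tolower(material)]]
  if (is.null(m))
    stop(sprintf("unknown material '%s'; supported: %s", material,
                 paste(names(.MATERIALS), collapse = ", ")))
  m
}

## mass coefficient of a compound in cm^2/g
.massCoef <- function(material, energyKeV, what = c("mu", "muen")) {
  what <- match.arg(what)
  m <- .materialSpec(material)
  comp <- m$composition
  sum(vapply(names(comp),
             function(s) comp[[s]] * .elementCoef(s, energyKeV, what),
             numeric(1)))
}

## electrons per m^3
.electronDensity <- function(material) {
  m <- .materialSpec(material)
  comp <- m$composition
  za <- sum(vapply(names(comp), function(s) comp[[s]] * .ELEMENTS[[s]]$ZA,
                   numeric(1)))
  m$density * 1e6 * .N_AVOGADRO * za   # density g/cm^3 -> g/m^3 times N_A/A*Z
}

#' X-ray optical constants of a material
#'
#' Returns the refractive-index decrement delta, the imaginary part beta,
#' the linear attenuation coefficient mu and the mass energy-absorption
#' coefficient mu_en/rho at the requested photon energy. delta is computed
#' from the electron density (valid away from absorption edges); mu and
#' mu_en/rho come from embedded standard tables with log-log interpolation,
#' and beta = mu * lambda / (4 pi) so that mu = 4 pi beta / lambda holds
#' exactly.
#'
#' @param material one of \code{\link{supportedMaterials}()}
#' @param energyKeV photon energy in keV (within the material's table span:
#'   5-30 keV for light materials, 12.5-30 keV for tungsten and tantalum)
#' @return an \linkS4class{OpticalConstants}
#' @examples
#' opticalConstants("beryllium", 10)     # delta ~ 3.4e-6
#' opticalConstants("water", 12.7)       # mu_en/rho ~ 0.232 m^2/kg
#' @export
opticalConstants <- function(material, energyKeV) {
  if (!is.numeric(energyKeV) || length(energyKeV) != 1L || energyKeV <= 0)
    stop("energyKeV must be a positive scalar")
  m <- .materialSpec(material)
  lambda <- wavelengthFromEnergy(energyKeV)
  delta <- .R_E * lambda^2 * .electronDensity(material) / (2 * pi)
  muRho <- .massCoef(material, energyKeV, "mu")        # cm^2/g
  mu <- muRho * m$density * 100                        # 1/m
  muEnRho <- .massCoef(material, energyKeV, "muen") / 10  # m^2/kg
  new("OpticalConstants", material = tolower(material), energy = energyKeV,
      delta = delta, beta = mu * lambda / (4 * pi), mu = mu,
      muEnRho = muEnRho, density = m$density * 1000)
}
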