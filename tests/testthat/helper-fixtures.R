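# shared fixtures, built in code

# small crystals-in-LCP phantom for fast pipeline tests
tinyPhantom <- function(nCrystals = 3, n = 64, seed = 11) {
  makeCrystalMountPhantom(nCrystals = nCrystals, dim = rep(n, 3),
                          voxelSize = 2.4e-6, slabWidth = 110e-6,
                          slabThickness = 90e-6,
                          sizeRange = c(10e-6, 22e-6), seed = seed)
}

# analytic parallel-beam sinogram of a disk of radius R (m) and attenuation
# mu (1/m), centred at (x0, y0) pixels off the rotation axis
diskSinogram <- function(nu = 128, anglesDeg = 0:179, R = 30e-6, mu = 1000,
                         x0 = 0, y0 = 0, pitch = 1e-6) {
  ctr <- (nu - 1) / 2
  th <- anglesDeg * pi / 180
  t(vapply(th, function(t0) {
    s <- ((0:(nu - 1)) - ctr - (x0 * cos(t0) + y0 * sin(t0))) * pitch
    2 * mu * sqrt(pmax(R^2 - s^2, 0))
  }, numeric(nu)))
}

# analytic disk image matching diskSinogram conventions
diskImage <- function(nu = 128, R = 30e-6, mu = 1000, x0 = 0, y0 = 0,
                      pitch = 1e-6) {
  xi <- ((1:nu) - 0.5) - nu / 2
  outer(xi, xi, function(x, y)
    ifelse((x - x0)^2 + (y - y0)^2 <= (R / pitch)^2, mu, 0))
}

# one-voxel phantom of a given material, for projection unit tests
monoVoxelPhantom <- function(n = 16, at = c(8, 8, 8), material = "water",
                             voxelSize = 1e-6) {
  lab <- array(0L, rep(n, 3))
  lab[at[1], at[2], at[3]] <- 1L
  new("VoxelPhantom", labels = lab, voxelSize = voxelSize,
      materials = data.frame(label = 1L, material = material,
                             role = "matrix", stringsAsFactors = FALSE),
      groundTruth = list(count = 0L,
                         centroids = matrix(numeric(0), 0, 3),
                         volumes = integer(0)))
}
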