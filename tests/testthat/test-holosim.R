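test_that("projection-approximation transmission", {
  zero <- new("ThicknessMaps",
              maps = list(water = matrix(0, 8, 8)), pitch = 1e-6, angle = 0)
  f <- transmit(zero, 12.7)
  expect_true(all(f@data == 1 + 0i))
  # Beer-Lambert intensity for 50 um of water
  slab <- new("ThicknessMaps",
              maps = list(water = matrix(50e-6, 4, 4)), pitch = 1e-6,
              angle = 0)
  oc <- opticalConstants("water", 12.7)
  I <- Mod(transmit(slab, 12.7)@data)^2
  expect_equal(unique(as.vector(I)), exp(-oc@mu * 50e-6), tolerance = 1e-9)
  # phase advances by -2 pi delta t / lambda (compare modulo 2 pi)
  want <- -2 * pi * oc@delta * 50e-6 / wavelengthFromEnergy(12.7)
  got <- unique(as.vector(Arg(transmit(slab, 12.7)@data)))
  expect_length(got, 1L)
  expect_lt(abs(exp(1i * got) - exp(1i * want)), 1e-9)
})

test_that("Fresnel propagation conserves energy, composes, and is exact in its trivial limits", {
  maps <- makeFiberPhantom(field = c(1024L, 1L), pixel = 1.2e-6)
  f <- transmit(maps, 12.7)
  expect_identical(propagate(f, 0), f)
  u <- new("ComplexField", data = matrix(complex(modulus = 2, argument = 1),
                                         64, 64), pitch = 1e-6,
           wavelength = 1e-10)
  pu <- propagate(u, 0.5)
  expect_equal(pu@data, u@data, tolerance = 1e-9)   # plane wave unchanged
  p1 <- propagate(f, 0.7)
  expect_equal(sum(Mod(p1@data)^2) / sum(Mod(f@data)^2), 1,
               tolerance = 1e-6)
  p2 <- propagate(propagate(f, 0.3), 0.4)
  expect_equal(max(Mod(p2@data - p1@data)), 0, tolerance = 1e-6)
  expect_error(propagate(f, 50), "sampling")
})

test_that("phase-edge fringes appear on the Fresnel-length scale", {
  # pi/2 phase step, 12.7 keV, z = 5 m: sqrt(lambda z) = 22 um
  n <- 4096L; pitch <- 0.6e-6
  x <- ((seq_len(n) - 0.5) - n / 2) * pitch
  field <- new("ComplexField",
               data = matrix(exp(1i * (pi / 2) * (x > 0)), n, 1),
               pitch = pitch, wavelength = wavelengthFromEnergy(12.7))
  I <- Mod(propagate(field, 5)@data[, 1])^2
  fresnel <- sqrt(wavelengthFromEnergy(12.7) * 5)
  expect_equal(fresnel, 2.2e-5, tolerance = 0.01)
  right <- which(x > 0 & x < 100e-6)
  imax <- right[which.max(I[right])]
  # first bright fringe within a couple of Fresnel lengths of the edge
  expect_lt(x[imax], 3 * fresnel)
  expect_gt(max(I[right]), 1.05)   # genuine fringes, not flat
})

test_that("partial-coherence blur: identity limits, mean preservation, width", {
  set.seed(8)
  img <- matrix(runif(64 * 64), 64, 64)
  expect_identical(applyPartialCoherence(img, 1e-6, 0, dEffV = 35e-6,
                                         distance = 61), img)
  expect_identical(applyPartialCoherence(img, 1e-6, 5, dEffV = 0,
                                         distance = 61), img)
  b <- applyPartialCoherence(img, 1e-6, 5, dEffV = 35e-6, distance = 61)
  expect_equal(mean(b), mean(img), tolerance = 1e-9)
  # blur FWHM = d_eff z / L = 2.87 um at the fiber geometry
  n <- 1024L; pitch <- 0.2e-6
  delta <- matrix(0, n, 1); delta[n / 2, 1] <- 1
  bl <- applyPartialCoherence(delta, pitch, 5, dEffV = 35e-6, distance = 61)
  prof <- bl[, 1] / max(bl[, 1])
  fwhmPx <- sum(prof >= 0.5)
  expect_equal(fwhmPx * pitch * 1e6, 35 * 5 / 61, tolerance = 0.1)
})

test_that("fringe visibility decreases monotonically with source size", {
  vis <- vapply(c(0, 20e-6, 35e-6, 50e-6), function(d) {
    p <- modelProfile(d)@intensities
    max(p) - min(p)
  }, numeric(1))
  expect_true(all(diff(vis) < 0))
})

test_that("hologram recording: counts, expectation, Poisson consistency", {
  I <- matrix(1, 4, 4)
  h0 <- record(I, NULL, 1e13, 0, 12.7, 0.6e-6)
  expect_true(all(imageData(h0) == 0))
  # expected counts at the imaging flux: 1e13 * 3.6e-7 mm^2 * 17 ms
  he <- record(I, NULL, 1e13, 0.017, 12.7, 0.6e-6)
  expect_equal(unique(as.vector(imageData(he))), 1e13 * 0.017 * 3.6e-7,
               tolerance = 1e-9)
  # expectation equals the mean of seeded draws within 3 standard errors
  lambda <- 200
  hp <- record(matrix(lambda / (1e13 * 0.017 * 3.6e-7), 100, 100), NULL,
               1e13, 0.017, 12.7, 0.6e-6, seed = 21)
  se <- sqrt(lambda / 1e4)
  expect_lt(abs(mean(imageData(hp)) - lambda), 3 * se)
  # reproducible draws
  h1 <- record(I, NULL, 1e13, 0.017, 12.7, 0.6e-6, seed = 5)
  h2 <- record(I, NULL, 1e13, 0.017, 12.7, 0.6e-6, seed = 5)
  expect_identical(imageData(h1), imageData(h2))
})

test_that("tomographic series simulation composes the forward chain", {
  ph <- tinyPhantom(nCrystals = 2, n = 48, seed = 2)
  flats <- makeFlatFields(3, field = c(48, 48), pitch = voxelSize(ph),
                          seed = 3)
  sim <- simulateTomoSeries(ph, nAngles = 1, flats = flats, seed = NULL)
  # manual chain at angle 0 must agree exactly
  maps <- projectThickness(ph, 0)
  field <- propagate(transmit(maps, 12.7), 0.11)
  intens <- applyPartialCoherence(Mod(field@data)^2, voxelSize(ph), 0.11,
                                  source = SourceModel())
  manual <- record(intens, flats[[1]], 1e13, 0.017, 12.7, voxelSize(ph),
                   0.11)
  expect_equal(sim$stack@frames[, , 1], imageData(manual), tolerance = 1e-12)
  # empty phantom: projections equal the flat-field expectation
  lab <- array(0L, c(32, 32, 32))
  empty <- new("VoxelPhantom", labels = lab, voxelSize = 2.4e-6,
               materials = data.frame(label = 1L, material = "lcp",
                                      role = "matrix",
                                      stringsAsFactors = FALSE),
               groundTruth = list(count = 0L,
                                  centroids = matrix(numeric(0), 0, 3),
                                  volumes = integer(0)))
  flats32 <- makeFlatFields(2, field = c(32, 32), pitch = 2.4e-6, seed = 5)
  sime <- simulateTomoSeries(empty, nAngles = 2, flats = flats32,
                             seed = NULL)
  expect_equal(sime$stack@frames[, , 1],
               imageData(sime$flatImages[[sime$flatIndex[1]]]),
               tolerance = 1e-12)
  # seeded runs are reproducible
  s1 <- simulateTomoSeries(ph, nAngles = 2, flats = flats, seed = 17)
  s2 <- simulateTomoSeries(ph, nAngles = 2, flats = flats, seed = 17)
  expect_identical(s1$stack@frames, s2$stack@frames)
})
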