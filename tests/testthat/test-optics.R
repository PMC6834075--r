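test_that("energy-wavelength conversion follows hc/E", {
  expect_equal(wavelengthFromEnergy(12.398420) * 1e10, 1.0, tolerance = 1e-6)
  expect_equal(wavelengthFromEnergy(12.7) * 1e10, 12.398420 / 12.7,
               tolerance = 1e-9)
  expect_equal(wavelengthFromEnergy(10) * 1e10, 1.2398420, tolerance = 1e-6)
  expect_error(wavelengthFromEnergy(0), "positive")
  expect_error(wavelengthFromEnergy(-3), "positive")
})

test_that("Beam locks wavelength to energy and validates", {
  b <- Beam(12.7)
  expect_s4_class(b, "Beam")
  expect_equal(photonEnergy(b), 12.7)
  expect_equal(b@energy * beamWavelength(b) * 1e10, 12.39842,
               tolerance = 1e-4)
  expect_error(new("Beam", energy = 10, wavelength = 2e-10), "hc")
})

test_that("transverse coherence length reproduces beamline figures", {
  # measured effective source: 35 um at 61 m, 12.7 keV -> 170 um
  expect_equal(coherenceLength(Beam(12.7), 61, 35e-6) * 1e6, 170,
               tolerance = 0.01)
  # nominal horizontal source 330 um at 12 keV -> ~19 um
  expect_equal(coherenceLength(Beam(12), 61, 330e-6) * 1e6, 19.1,
               tolerance = 0.005)
  # l_c is inversely proportional to the source size
  lc1 <- coherenceLength(Beam(12.7), 61, 20e-6)
  expect_equal(coherenceLength(Beam(12.7), 61, 40e-6), lc1 / 2)
  expect_error(coherenceLength(Beam(12.7), 61, 0), "positive")
})

test_that("maximum source size under the factor-15 criterion", {
  b1A <- Beam(12.398420)   # lambda = 1 Angstrom
  expect_equal(maxSourceSize(1e-6, b1A, 60) * 1e6, 400, tolerance = 1e-6)
  # d_max = lambda L / (15 Delta) is inversely proportional to the target
  # resolution: relaxing Delta to 2 um halves the admissible source size
  expect_equal(maxSourceSize(2e-6, b1A, 60) * 1e6, 200, tolerance = 1e-6)
  expect_equal(maxSourceSize(1e-6, b1A, 60, coherenceFactor = 1),
               15 * maxSourceSize(1e-6, b1A, 60))
})

test_that("coherence length and max source size are algebraic inverses", {
  b <- Beam(17.3)
  for (delta in c(0.3e-6, 1e-6, 5e-6)) {
    d <- maxSourceSize(delta, b, 48)
    expect_equal(coherenceLength(b, 48, d), 15 * delta, tolerance = 1e-12)
  }
})

test_that("monochromator broadening adds in FWHM quadrature", {
  # oracle: sqrt(13^2 + (0.7e-6 * 45e6)^2) um = 34.08 um
  expect_equal(effectiveSourceSize(13e-6, 0.7e-6, 45) * 1e6,
               sqrt(13^2 + 31.5^2), tolerance = 1e-9)
  expect_equal(effectiveSourceSize(330e-6, 0.7e-6, 45) * 1e6,
               sqrt(330^2 + 31.5^2), tolerance = 1e-9)  # ~331.5: barely moved
  expect_equal(effectiveSourceSize(21e-6, 0, 45), 21e-6)
  # quadrature lower bounds
  for (d in c(5e-6, 50e-6)) for (s in c(0, 1e-6)) {
    de <- effectiveSourceSize(d, s, 45)
    expect_gte(de, max(d, s * 45) - 1e-15)
  }
})

test_that("optical constants reproduce reference anchors", {
  be <- opticalConstants("beryllium", 10)
  expect_equal(be@delta, 3.41e-6, tolerance = 0.005)
  w <- opticalConstants("water", 12.7)
  expect_equal(w@muEnRho, 0.232, tolerance = 0.01)   # 2.32 cm^2/g
  # internal consistency mu = 4 pi beta / lambda for all materials
  for (m in supportedMaterials()) {
    e <- if (m %in% c("tungsten", "tantalum")) 15 else 12.7
    oc <- opticalConstants(m, e)
    expect_equal(oc@mu, 4 * pi * oc@beta / wavelengthFromEnergy(e),
                 tolerance = 1e-3)
  }
  expect_error(opticalConstants("adamantium", 10), "adamantium")
  expect_error(opticalConstants("tungsten", 8), "span")
  expect_error(opticalConstants("water", 2), "span")
})

test_that("CRL focal length matches R/(2 N delta) and scales as E^2", {
  stack10 <- CRLStack(20, 50e-6, "beryllium", 10)
  expect_equal(crlFocalLength(stack10), 0.37, tolerance = 0.02)
  stack1 <- CRLStack(1, 50e-6, "beryllium", 10)
  expect_equal(crlFocalLength(stack1), 20 * crlFocalLength(stack10),
               tolerance = 1e-12)
  stack127 <- CRLStack(20, 50e-6, "beryllium", 12.7)
  expect_equal(crlFocalLength(stack127) / crlFocalLength(stack10),
               (12.7 / 10)^2, tolerance = 1e-6)
  expect_equal(crlFocalLength(stack127), 0.59, tolerance = 0.01)
})

test_that("thin-lens solver", {
  expect_equal(thinLensSolve(L1 = 0.40, L2 = 4.56), 1 / (1/0.4 + 1/4.56),
               tolerance = 1e-12)                        # ~36.8 cm
  expect_equal(thinLensSolve(F = 1, L1 = 2), 2)          # 2F-2F symmetry
  expect_equal(thinLensSolve(F = 0.3665, L1 = 0.40), 4.376, tolerance = 1e-3)
  expect_error(thinLensSolve(F = 0.5, L1 = 0.4), "no real image")
  expect_error(thinLensSolve(F = 1), "exactly two")
  # round trip: F -> L2 -> F recovers the input to 1e-6 relative
  for (F in c(0.2, 0.3665)) {
    L2 <- thinLensSolve(F = F, L1 = 0.5)
    expect_equal(thinLensSolve(L1 = 0.5, L2 = L2), F, tolerance = 1e-6)
  }
})

test_that("magnification and effective pixel size", {
  m <- magnificationAndPixel(0.40, 4.56, 0.6e-6)
  expect_equal(m$magnification, 11.4, tolerance = 1e-12)
  expect_equal(m$effectivePixel * 1e9, 52.63, tolerance = 1e-3)
  m1 <- magnificationAndPixel(0.40, 0.40, 0.6e-6)
  expect_equal(m1$magnification, 1)
  expect_equal(m1$effectivePixel, 0.6e-6)
  m2 <- magnificationAndPixel(0.40, 9.12, 0.6e-6)
  expect_equal(m2$magnification, 22.8)
  expect_equal(m2$effectivePixel * 1e9, 26.3, tolerance = 1e-2)
})

test_that("CRL effective aperture and diffraction limit", {
  stack <- CRLStack(20, 50e-6, "beryllium", 10)
  r <- crlResolution(stack, 0.40)
  expect_lt(abs(r$effectiveAperture - 270e-6) / 270e-6, 0.25)
  # with the aperture pinned to the quoted 270 um the limit is ~138 nm
  lambda <- wavelengthFromEnergy(10)
  expect_equal(0.75 * lambda * 0.40 / 270e-6 * 1e9, 137.8, tolerance = 1e-3)
  # delta_res doubles when A_eff halves
  r2 <- crlResolution(stack, 0.40, correction = 0.5)
  expect_equal(r2$diffractionLimit, 2 * r$diffractionLimit,
               tolerance = 1e-12)
})
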