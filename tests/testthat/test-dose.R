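test_that("thin-sample dose reproduces the imaging dose scale", {
  spec <- ExposureSpec(fluxDensity = 1e13, time = 0.017, energyKeV = 12.7)
  d <- doseFromExposure(spec, "water")
  expect_equal(doseGray(d), 80, tolerance = 0.05)
  # 180-projection tomography accumulates exactly 180x
  tomo <- ExposureSpec(fluxDensity = 1e13, time = 0.017, energyKeV = 12.7,
                       nRepeats = 180)
  expect_equal(doseGray(doseFromExposure(tomo)), 180 * doseGray(d),
               tolerance = 1e-12)
  expect_equal(doseGray(doseFromExposure(tomo)) / 1e3, 15, tolerance = 0.05)
  # zero exposure deposits nothing
  z <- ExposureSpec(fluxDensity = 1e13, time = 0, energyKeV = 12.7)
  expect_identical(doseGray(doseFromExposure(z)), 0)
})

test_that("dose is linear in flux density, time and repeats, and monotone in mu_en/rho", {
  base <- doseGray(doseFromExposure(
    ExposureSpec(fluxDensity = 1e12, time = 0.1, energyKeV = 12.7)))
  expect_equal(doseGray(doseFromExposure(
    ExposureSpec(fluxDensity = 3e12, time = 0.1, energyKeV = 12.7))),
    3 * base, tolerance = 1e-12)
  expect_equal(doseGray(doseFromExposure(
    ExposureSpec(fluxDensity = 1e12, time = 0.4, energyKeV = 12.7))),
    4 * base, tolerance = 1e-12)
  expect_equal(doseGray(doseFromExposure(
    ExposureSpec(fluxDensity = 1e12, time = 0.1, energyKeV = 12.7,
                 nRepeats = 7))), 7 * base, tolerance = 1e-12)
  # at fixed fluence, a larger mu_en/rho absorbs more
  spec <- ExposureSpec(fluxDensity = 1e12, time = 0.1, energyKeV = 12.7)
  muen <- vapply(c("lcp", "water", "protein"), function(m)
    opticalConstants(m, 12.7)@muEnRho, numeric(1))
  doses <- vapply(c("lcp", "water", "protein"), function(m)
    doseGray(doseFromExposure(spec, m)), numeric(1))
  expect_equal(order(doses), order(muen))
})

test_that("ExposureSpec validates flux / area consistency", {
  sp <- ExposureSpec(flux = 1.5e12, areaMm2 = 0.054^2, time = 1,
                     energyKeV = 10)
  expect_equal(sp@fluxDensity, 5.1e14, tolerance = 0.01)
  expect_error(new("ExposureSpec", fluxDensity = 1, flux = 10, areaMm2 = 1,
                   time = 1, energy = 10, nRepeats = 1), "inconsistent")
})

test_that("scenario dose report derives the standard table quantities", {
  rep <- doseReport()
  img <- rep[rep$scenario == "imaging (single shot)", ]
  expect_equal(img$flux_density_ph_s_mm2, 1e13, tolerance = 0.07)
  micro <- rep[rep$scenario == "microscopy (single shot)", ]
  expect_equal(micro$flux_density_ph_s_mm2, 5.1e14, tolerance = 0.01)
  expect_equal(micro$dose_kGy, 330, tolerance = 0.25)
  tomo <- rep[rep$scenario == "tomography (180 projections)", ]
  expect_equal(tomo$total_exposure_s, 3, tolerance = 0.03)
  expect_equal(tomo$dose_kGy, 15, tolerance = 0.05)
})
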