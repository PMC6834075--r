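test_that("profile extraction averages columns and reduces noise", {
  const <- new("Hologram", data = matrix(7, 64, 16), pitch = 1e-6, z = 1,
               energy = 12.7, fluxDensity = NA_real_, exposure = NA_real_,
               seed = NA_real_)
  p <- extractProfile(const, nColumns = 10)
  expect_true(all(abs(p@intensities - 1) < 1e-12))  # normalized constant
  expect_error(extractProfile(const, nColumns = 32), "exceeds")

  # Poisson noise drops by ~sqrt(nColumns) under column averaging
  lambda <- 1e4
  img <- matrix(rpois(512 * 40, lambda), 512, 40)
  h <- new("Hologram", data = img + 0.0, pitch = 1e-6, z = 1, energy = 12.7,
           fluxDensity = NA_real_, exposure = NA_real_, seed = NA_real_)
  p1 <- extractProfile(h, nColumns = 1)
  p10 <- extractProfile(h, nColumns = 10)
  ratio <- sd(p1@intensities) / sd(p10@intensities)
  expect_gt(ratio, sqrt(10) * 0.7)
  expect_lt(ratio, sqrt(10) * 1.4)
})

test_that("simulated fiber profile is symmetric and far field is flat", {
  h <- simulateFiberHologram(dEff = 35e-6, seed = 31)
  p <- extractProfile(h)
  y <- p@intensities
  n <- length(y)
  # symmetry about the fiber axis within counting noise
  asym <- mean(abs(y - rev(y))) / mean(y)
  expect_lt(asym, 0.02)
  # far from the fiber (> 3 Fresnel lengths past the edge) the profile is 1
  far <- abs(p@positions) > 50e-6 + 3 * 2.2e-5 + 150e-6
  m <- modelProfile(35e-6)
  expect_true(all(abs(m@intensities[far] - 1) < 0.01))
})

test_that("source-size fit recovers the truth", {
  # self-consistency on the noiseless model
  f0 <- fitSourceSize(modelProfile(35e-6))
  expect_equal(fittedSourceSize(f0) * 1e6, 35, tolerance = 0.01)
  expect_false(f0@boundary)
  # residual trace is unimodal for the noiseless target
  tr <- fitTrace(f0)
  coarse <- tr[seq_len(which.min(abs(tr$dEff - 5e-6)) + 0), ]
  r <- tr$residual[order(tr$dEff)]
  imin <- which.min(r)
  expect_true(all(diff(r[seq_len(imin)]) <= 1e-12) ||
                all(diff(r[seq_len(imin)]) <= 0 + 1e-9 * max(r)))
  expect_true(all(diff(r[imin:length(r)]) >= -1e-9 * max(r)))

  # noisy recovery at the standard flux/exposure
  for (truth in c(20e-6, 35e-6, 50e-6)) {
    h <- simulateFiberHologram(dEff = truth, seed = 100 + round(truth * 1e6))
    fit <- fitSourceSize(extractProfile(h))
    expect_lt(abs(fittedSourceSize(fit) - truth), 3e-6)
    expect_false(fit@boundary)
  }
})

test_that("fit flags a boundary minimum", {
  h <- simulateFiberHologram(dEff = 3e-6, seed = 9)  # below the search range
  expect_warning(fit <- fitSourceSize(extractProfile(h)), "boundary")
  expect_true(fit@boundary)
})
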