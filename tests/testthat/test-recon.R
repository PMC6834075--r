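test_that("center finding: recovery, equivariance, symmetry", {
  ph <- tinyPhantom(seed = 3)
  arr <- array(0, c(64, 64, 180))
  mv <- phaseCT:::.materialVolume(ph)
  for (a in 1:180)
    arr[, , a] <- Reduce(`+`,
                         phaseCT:::.projectMaterialVolume(mv, a - 1,
                                                          voxelSize(ph))@maps)
  ctr <- findCenter(arr, 0:179)
  expect_lt(abs(ctr - (64 - 1) / 2), 0.5)   # symmetric grid: (width-1)/2
  # shifting all projections shifts the recovered center equally
  sh <- arr[, c(4:64, 1:3), ]               # content moves left by 3 px
  expect_equal(findCenter(sh, 0:179) - ctr, -3, tolerance = 0.5)
  expect_error(findCenter(arr[, , 1:90], 0:89), "179")
})

test_that("FBP of an analytic disk sinogram matches the disk", {
  nu <- 128; pitch <- 1e-6; mu <- 1000
  sino <- diskSinogram(nu = nu, R = 30e-6, mu = mu, x0 = 10.5, y0 = -7.25,
                       pitch = pitch)
  tomo <- reconstruct(new("Sinogram", data = sino, angles = 0:179,
                          center = (nu - 1) / 2), pitch = pitch)
  sl <- imageData(tomo)[, , 1]
  truth <- diskImage(nu = nu, R = 30e-6, mu = mu, x0 = 10.5, y0 = -7.25,
                     pitch = pitch)
  expect_lt(sqrt(mean((sl - truth)^2)) / mu, 0.05)
  xi <- ((1:nu) - 0.5) - nu / 2
  interior <- outer(xi, xi, function(x, y)
    (x - 10.5)^2 + (y + 7.25)^2) <= (0.7 * 30)^2
  expect_lt(abs(mean(sl[interior]) / mu - 1), 0.03)
  # zero sinogram reconstructs to zero
  z <- reconstruct(new("Sinogram", data = sino * 0, angles = 0:179,
                       center = (nu - 1) / 2), pitch = pitch)
  expect_true(all(imageData(z) == 0))
})

test_that("reconstruction is linear", {
  s1 <- diskSinogram(nu = 64, R = 12e-6, x0 = 5, y0 = 3)
  s2 <- diskSinogram(nu = 64, R = 18e-6, x0 = -8, y0 = -2, mu = 500)
  r <- function(s) imageData(reconstruct(new("Sinogram", data = s,
                                             angles = 0:179,
                                             center = 31.5),
                                         pitch = 1e-6))[, , 1]
  sum2 <- r(s1 + s2)
  lin <- r(s1) + r(s2)
  expect_lt(max(abs(sum2 - lin)) / max(abs(lin)), 1e-6)
})

test_that("reconstruct validates angle spacing", {
  s <- diskSinogram(nu = 32, anglesDeg = c(0, 1, 3, 6), R = 8e-6)
  expect_error(reconstruct(new("Sinogram", data = s,
                               angles = c(0, 1, 3, 6), center = 15.5),
                           pitch = 1e-6), "non-uniform")
})
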