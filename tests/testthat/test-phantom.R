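test_that("fiber phantom chord thicknesses", {
  maps <- makeFiberPhantom(field = c(2048L, 4L))
  tB <- maps@maps$boron[, 1]
  tW <- maps@maps$tungsten[, 1]
  n <- length(tB)
  x <- ((seq_len(n) - 0.5) - n / 2) * 0.6e-6
  i0 <- which.min(abs(x))                      # closest sample to the axis
  # chord through the centre spans the full diameter, split shell/core
  expect_equal((tB[i0] + tW[i0]) * 1e6, 100, tolerance = 0.01)
  expect_equal(tB[i0] * 1e6, 85, tolerance = 0.02)
  # core chord vanishes at |x| >= 7.5 um
  expect_true(all(tW[abs(x) >= 7.5e-6] == 0))
  expect_gt(tW[i0], 14.9e-6)
  expect_true(all(tB >= 0) && all(tW >= 0))
  expect_error(makeFiberPhantom(coreDiameter = 120e-6), "smaller")
  expect_error(makeFiberPhantom(field = c(256L, 4L)), "margin")
})

test_that("crystal-mount phantom is reproducible and respects its contract", {
  ph1 <- tinyPhantom(seed = 7)
  ph2 <- tinyPhantom(seed = 7)
  expect_identical(imageData(ph1), imageData(ph2))
  gt <- groundTruth(ph1)
  expect_equal(gt$count, 3L)
  expect_equal(nrow(gt$centroids), 3L)
  # ground-truth volumes match the labelled voxels
  for (i in 1:3)
    expect_equal(gt$volumes[i], sum(imageData(ph1) == 2L + i))
  # no crystals: only background, matrix and mount labels remain
  ph0 <- makeCrystalMountPhantom(nCrystals = 0, dim = c(32, 32, 32),
                                 voxelSize = 4e-6, slabWidth = 60e-6,
                                 slabThickness = 40e-6, seed = 1)
  expect_true(all(unique(as.integer(imageData(ph0))) %in% 0:2))
  expect_equal(groundTruth(ph0)$count, 0L)
  expect_error(makeCrystalMountPhantom(sizeRange = c(1e-6, 2e-6),
                                       voxelSize = 2.4e-6), "3 voxels")
})

test_that("study-condition phantom has the full crystal count as connected components", {
  ph <- makeCrystalMountPhantom(seed = 42)   # defaults: 20 crystals, 256^3
  gt <- groundTruth(ph)
  expect_equal(gt$count, 20L)
  lab <- imageData(ph)
  d <- dim(lab)
  cc <- phaseCT:::cpp_label3d(lab >= 3L, d[1], d[2], d[3])
  expect_equal(max(cc), 20L)
})

test_that("parallel projection: single voxel, symmetry, Cavalieri identity", {
  ph <- monoVoxelPhantom()
  tm <- projectThickness(ph, 0)
  m <- tm@maps$water
  expect_equal(sum(m > 0), 1L)
  expect_equal(max(m), 1e-6)
  expect_equal(which(m > 0, arr.ind = TRUE)[1, ], c(row = 8L, col = 8L))
  # 0 and 180 degrees are mirror images for any phantom
  ph3 <- tinyPhantom(seed = 3)
  p0 <- projectThickness(ph3, 0)@maps$protein
  p180 <- projectThickness(ph3, 180)@maps$protein
  expect_equal(p0, p180[, rev(seq_len(ncol(p180)))], tolerance = 1e-6)
  # Cavalieri: projected volume equals voxel volume at any angle, for
  # material inside the reconstruction circle
  vx <- voxelSize(ph3)
  for (ang in c(0, 17.3, 45, 90)) {
    tm <- projectThickness(ph3, ang)
    pv <- sum(tm@maps$protein) * vx^2
    nv <- sum(imageData(ph3) >= 3L) * vx^3
    expect_equal(pv, nv, tolerance = 0.005)
  }
})

test_that("flat-field pool construction", {
  flats <- makeFlatFields(30, field = c(64, 64), seed = 9)
  expect_length(flats, 30L)
  expect_true(all(vapply(flats, function(f) all(imageData(f) > 0),
                         logical(1))))
  # distinct fields
  expect_gt(max(abs(imageData(flats[[1]]) - imageData(flats[[2]]))), 0)
  # amplitude 0, dispersion 0 gives exact unit gain
  ones <- makeFlatFields(2, field = c(16, 16), structureAmplitude = 0,
                         gainDispersion = 0, seed = 1)
  expect_true(all(imageData(ones[[1]]) == 1))
  # defaults: mean-normalized pairwise correlation in (0.9, 1)
  set.seed(1)
  pairs <- cbind(sample(30, 8, TRUE), sample(30, 8, TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  for (r in seq_len(nrow(pairs))) {
    a <- imageData(flats[[pairs[r, 1]]]); a <- a / mean(a)
    b <- imageData(flats[[pairs[r, 2]]]); b <- b / mean(b)
    expect_gt(cor(as.vector(a), as.vector(b)), 0.9)
    expect_lt(cor(as.vector(a), as.vector(b)), 1)
  }
  # reproducible
  expect_identical(imageData(makeFlatFields(3, c(32, 32), seed = 5)[[2]]),
                   imageData(makeFlatFields(3, c(32, 32), seed = 5)[[2]]))
})
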