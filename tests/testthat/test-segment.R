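test_that("two bright cubes segment into two correct regions", {
  vol <- array(0, c(40, 40, 40))
  vol[5:10, 5:10, 5:10] <- 1
  vol[25:32, 20:27, 15:22] <- 1.2
  tomo <- new("Tomogram", data = vol, voxelSize = 1e-6)
  seg <- segment(tomo, rule = "otsu", minSize = 8, smoothSigma = 0)
  tab <- regionTable(seg)
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$voxels, c(6^3, 8^3))
  big <- tab[which.max(tab$voxels), ]
  expect_equal(c(big$cx, big$cy, big$cz), c(28.5, 23.5, 18.5))
})

test_that("size, edge and threshold options behave", {
  vol <- array(0, c(24, 24, 24))
  vol[2:4, 2:4, 2:4] <- 1          # small
  vol[10:16, 10:16, 10:16] <- 1    # large
  vol[1, 20:24, 20:24] <- 1        # touches the border
  tomo <- new("Tomogram", data = vol, voxelSize = 1e-6)
  seg <- segment(tomo, threshold = 0.5, minSize = 30, smoothSigma = 0)
  expect_equal(nrow(regionTable(seg)), 1L)          # small + border dropped
  segAll <- segment(tomo, threshold = 0.5, minSize = 1, smoothSigma = 0,
                    excludeEdges = FALSE)
  expect_equal(nrow(regionTable(segAll)), 3L)
  expect_warning(segment(tomo, threshold = 2, smoothSigma = 0), "empty")
})

test_that("seeded watershed splits touching blobs", {
  n <- 32
  x <- seq_len(n)
  g <- expand.grid(x, x, x)
  d1 <- sqrt((g[, 1] - 12)^2 + (g[, 2] - 16)^2 + (g[, 3] - 16)^2)
  d2 <- sqrt((g[, 1] - 21)^2 + (g[, 2] - 16)^2 + (g[, 3] - 16)^2)
  vol <- array(pmax(exp(-d1^2 / 18), exp(-d2^2 / 18)), c(n, n, n))
  seeds <- array(0L, c(n, n, n))
  seeds[12, 16, 16] <- 1L
  seeds[21, 16, 16] <- 2L
  seg <- segment(new("Tomogram", data = vol, voxelSize = 1e-6),
                 threshold = 0.2, minSize = 10, smoothSigma = 0,
                 seeds = seeds, excludeEdges = FALSE)
  tab <- regionTable(seg)
  expect_equal(nrow(tab), 2L)
  # the flood splits the foreground into one region per seed, ordered along
  # the blob axis (the exact boundary depends on the flat saddle)
  cxs <- sort(tab$cx)
  expect_lt(abs(cxs[1] - 12), 4)
  expect_lt(abs(cxs[2] - 21), 4)
  expect_gt(min(tab$voxels), 100)
})

test_that("label volume mesh export writes valid, watertight OBJ", {
  lab <- array(0L, c(8, 8, 8))
  lab[3, 4, 5] <- 1L                       # single voxel -> cube
  lab[6:7, 6:7, 2:3] <- 2L
  lv <- new("LabelVolume", labels = lab,
            table = phaseCT:::.regionTable(lab), voxelSize = 1e-6)
  path <- tempfile(fileext = ".obj")
  rep <- exportMesh(lv, path)
  lines <- readLines(path)
  nv <- sum(startsWith(lines, "v "))
  nf <- sum(startsWith(lines, "f "))
  expect_equal(nv, rep$vertices)
  expect_equal(nf, rep$triangles)
  expect_equal(sum(grepl("^g region_", lines)), 2L)
  # single voxel contributes 8 corners; the 2x2x2 block has 26 surface
  # corners (the 3^3 corner grid minus its interior point)
  expect_equal(rep$vertices, 8 + 26)
  # watertight: in each region every edge is shared by exactly two triangles
  f <- do.call(rbind, strsplit(sub("^f ", "", lines[startsWith(lines, "f ")]),
                               " "))
  f <- matrix(as.integer(f), ncol = 3)
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(key) == 2))
  # 1-based indices within the vertex count
  expect_true(all(f >= 1 & f <= nv))
  expect_error(exportMesh(new("LabelVolume", labels = array(0L, c(2, 2, 2)),
                              table = phaseCT:::.regionTable(
                                array(0L, c(2, 2, 2))),
                              voxelSize = 1e-6), tempfile()), "no regions")
})
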