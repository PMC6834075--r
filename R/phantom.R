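#' @include AllClasses.R
NULL

## bilinear upsampling of a coarse (k x k) grid to (nr x nc)
.smoothField <- function(nr, nc, k = 6L) {
  z <- matrix(rnorm(k * k), k, k)
  xs <- seq(1, k, length.out = nc)
  ys <- seq(1, k, length.out = nr)
  # interpolate columns then rows
  zc <- t(apply(z, 1, function(row) approx(seq_len(k), row, xout = xs)$y))
  out <- apply(zc, 2, function(col) approx(seq_len(k), col, xout = ys)$y)
  out <- (out - mean(out))
  s <- stats::sd(out)
  if (s > 0) out / s else out * 0
}

#' Analytic boron-fiber phantom
#'
#' Projected chord thicknesses of a cylindrical fiber (shell material) with a
#' concentric core, axis horizontal: the classic coherence test object (a
#' 100 um boron fiber with a 15 um tungsten core). The shell thickness is
#' t_shell(x) = 2[sqrt(R^2-x^2) - sqrt(r^2-x^2) (inside the core)] and the
#' core t_core(x) = 2 sqrt(r^2-x^2), with x the vertical distance from the
#' axis.
#'
#' @param diameter fiber diameter (m)
#' @param coreDiameter core diameter (m), strictly smaller than diameter
#' @param pixel pixel pitch (m)
#' @param field image size in pixels c(rows, cols); the vertical extent must
#'   cover the fiber plus at least 200 um margin on both sides
#' @param material shell material id
#' @param coreMaterial core material id
#' @return a \linkS4class{ThicknessMaps} with one map per material
#' @examples
#' maps <- makeFiberPhantom(field = c(2048, 16))
#' @export
makeFiberPhantom <- function(diameter = 100e-6, coreDiameter = 15e-6,
                             pixel = 0.6e-6, field = c(2048L, 32L),
                             material = "boron", coreMaterial = "tungsten") {
  if (coreDiameter >= diameter)
    stop("coreDiameter must be smaller than diameter")
  if (diameter <= 0 || pixel <= 0) stop("diameter and pixel must be positive")
  nr <- as.integer(field[1]); nc <- as.integer(field[2])
  if (nr * pixel < diameter + 2 * 200e-6)
    stop(sprintf(
      "field too small: %.0f um vertical extent < fiber %.0f um + 2 x 200 um margin",
      nr * pixel * 1e6, diameter * 1e6))
  R <- diameter / 2
  r <- coreDiameter / 2
  x <- ((seq_len(nr) - 0.5) - nr / 2) * pixel   # vertical distance from axis
  chord <- function(rad) ifelse(abs(x) < rad, 2 * sqrt(pmax(rad^2 - x^2, 0)), 0)
  tCore <- chord(r)
  tShell <- chord(R) - tCore
  maps <- list(matrix(rep(tShell, nc), nr, nc),
               matrix(rep(tCore, nc), nr, nc))
  names(maps) <- c(material, coreMaterial)
  new("ThicknessMaps", maps = maps, pitch = pixel, angle = 0)
}

## voxelize one random convex polyhedron (intersection of a bounding sphere
## and `nPlanes` half-spaces); returns linear voxel indices
.voxelizeCrystal <- function(center, radius, dim, nPlanes = 14L) {
  normals <- matrix(rnorm(3 * nPlanes), nPlanes, 3)
  normals <- normals / sqrt(rowSums(normals^2))
  support <- radius * runif(nPlanes, 0.7, 1)
  rv <- ceiling(radius) + 1L
  ir <- seq(max(1L, floor(center[1] - rv)), min(dim[1], ceiling(center[1] + rv)))
  jr <- seq(max(1L, floor(center[2] - rv)), min(dim[2], ceiling(center[2] + rv)))
  kr <- seq(max(1L, floor(center[3] - rv)), min(dim[3], ceiling(center[3] + rv)))
  g <- expand.grid(i = ir, j = jr, k = kr)
  dx <- g$i - center[1]; dy <- g$j - center[2]; dz <- g$k - center[3]
  inside <- dx^2 + dy^2 + dz^2 <= radius^2
  for (p in seq_len(nPlanes)) {
    if (!any(inside)) break
    inside <- inside &
      (normals[p, 1] * dx + normals[p, 2] * dy + normals[p, 3] * dz) <=
      support[p]
  }
  sel <- which(inside)
  g$i[sel] + dim[1] * (g$j[sel] - 1L) + dim[1] * dim[2] * (g$k[sel] - 1L)
}

#' Synthetic crystals-in-LCP mount phantom
#'
#' Generates the standard study object of the package: an LCP (water-like
#' lipid mesophase) slab held by a thin kapton mount frame, containing
#' non-overlapping convex protein crystals (random polyhedra). The mount
#' frame extends to the lateral volume borders, as a real mesh mount spans
#' the field of view. Axis 3 is the vertical rotation axis. Reproducible for
#' a fixed seed.
#'
#' Labels: 0 background (air), 1 LCP matrix, 2 mount, 3..(2+n) one per
#' crystal.
#'
#' @param nCrystals number of crystals (>= 0)
#' @param sizeRange crystal diameter range (m); at least 3 voxels
#' @param slabThickness LCP slab thickness along the beam-normal direction (m)
#' @param slabWidth lateral extent of the LCP window (m)
#' @param voxelSize voxel edge (m)
#' @param dim volume dimensions in voxels c(nx, ny, nz)
#' @param mountThickness thickness of the kapton frame (m)
#' @param seed RNG seed (NULL leaves the RNG state alone)
#' @param maxTries packing attempts per crystal before giving up
#' @return a \linkS4class{VoxelPhantom}
#' @examples
#' ph <- makeCrystalMountPhantom(nCrystals = 3, dim = c(64, 64, 64),
#'                               voxelSize = 2.4e-6, slabWidth = 100e-6,
#'                               seed = 1)
#' groundTruth(ph)$count
#' @export
makeCrystalMountPhantom <- function(nCrystals = 20L,
                                    sizeRange = c(10e-6, 50e-6),
                                    slabThickness = 150e-6,
                                    slabWidth = 500e-6,
                                    voxelSize = 2.4e-6,
                                    dim = c(256L, 256L, 256L),
                                    mountThickness = 12e-6,
                                    seed = NULL,
                                    maxTries = 200L) {
  if (nCrystals < 0) stop("nCrystals must be >= 0")
  if (nCrystals > 0 && min(sizeRange) < 3 * voxelSize)
    stop("crystal sizes must span at least 3 voxels")
  dim <- as.integer(dim)
  .withSeed(seed, {
    labels <- array(0L, dim)
    cx <- dim[1] / 2 + 0.5; cy <- dim[2] / 2 + 0.5; cz <- dim[3] / 2 + 0.5
    halfT <- slabThickness / 2 / voxelSize
    halfW <- min(slabWidth / 2 / voxelSize, dim[1] / 2 - 1, dim[3] / 2 - 1)
    ii <- slice.index(labels, 1); jj <- slice.index(labels, 2)
    kk <- slice.index(labels, 3)
    inWindow <- abs(ii - cx) <= halfW & abs(kk - cz) <= halfW
    inSlabY <- abs(jj - cy) <= halfT
    labels[inSlabY & inWindow] <- 1L
    # kapton frame: everything outside the window, over the mount thickness,
    # in front of the slab; reaches the lateral borders
    mountHalf <- max(1, mountThickness / 2 / voxelSize)
    yMount <- cy - halfT - mountHalf
    inMountY <- abs(jj - yMount) <= mountHalf
    labels[inMountY & !inWindow] <- 2L
    rm(ii, jj, kk, inWindow, inSlabY, inMountY)

    centroids <- matrix(numeric(0), 0, 3,
                        dimnames = list(NULL, c("x", "y", "z")))
    volumes <- integer(0)
    if (nCrystals > 0) {
      radii <- runif(nCrystals, sizeRange[1], sizeRange[2]) / 2 / voxelSize
      centers <- matrix(NA_real_, nCrystals, 3)
      for (i in seq_len(nCrystals)) {
        placed <- FALSE
        for (try in seq_len(maxTries)) {
          m <- radii[i] + 2
          cand <- c(runif(1, cx - halfW + m, cx + halfW - m),
                    runif(1, cy - halfT + m, cy + halfT - m),
                    runif(1, cz - halfW + m, cz + halfW - m))
          if (i > 1L) {
            d <- sqrt(colSums((t(centers[seq_len(i - 1L), , drop = FALSE]) -
                                 cand)^2))
            if (any(d < radii[i] + radii[seq_len(i - 1L)] + 2)) next
          }
          centers[i, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed)
          stop(sprintf(
            "could not place crystal %d of %d after %d attempts; reduce the count or sizes",
            i, nCrystals, maxTries))
      }
      for (i in seq_len(nCrystals)) {
        idx <- integer(0)
        for (try in seq_len(maxTries)) {
          idx <- .voxelizeCrystal(centers[i, ], radii[i], dim)
          if (length(idx) >= 3L) break
        }
        if (length(idx) < 3L)
          stop(sprintf("crystal %d degenerated to < 3 voxels", i))
        labels[idx] <- 2L + i
        k <- idx - 1L
        xi <- k %% dim[1] + 1L
        yi <- (k %/% dim[1]) %% dim[2] + 1L
        zi <- k %/% (dim[1] * dim[2]) + 1L
        centroids <- rbind(centroids, c(mean(xi), mean(yi), mean(zi)))
        volumes <- c(volumes, length(idx))
      }
    }
    materials <- data.frame(
      label = c(1L, 2L, if (nCrystals > 0) 2L + seq_len(nCrystals)),
      material = c("lcp", "kapton", rep("protein", nCrystals)),
      role = c("matrix", "mount", rep("crystal", nCrystals)),
      stringsAsFactors = FALSE)
    new("VoxelPhantom", labels = labels, voxelSize = voxelSize,
        materials = materials,
        groundTruth = list(count = as.integer(nCrystals),
                           centroids = centroids, volumes = volumes))
  })
}

## collapse per-crystal labels to one material code (0 stays background)
.materialVolume <- function(phantom) {
  mats <- phantom@materials
  uniqMat <- unique(mats$material)
  code <- integer(max(mats$label) + 1L)
  code[mats$label + 1L] <- match(mats$material, uniqMat)
  list(vol = array(code[phantom@labels + 1L], dim(phantom@labels)),
       materials = uniqMat)
}

.projectMaterialVolume <- function(mv, angleDeg, voxelSize) {
  d <- dim(mv$vol)
  thick <- cpp_project_labels(mv$vol, d[1], d[2], d[3],
                              seq_along(mv$materials), angleDeg * pi / 180)
  maps <- lapply(seq_along(mv$materials), function(m)
    thick[, , m] * voxelSize)
  names(maps) <- mv$materials
  new("ThicknessMaps", maps = maps, pitch = voxelSize, angle = angleDeg)
}

#' Parallel projection of a voxel phantom
#'
#' Line integrals of per-material occupancy times the voxel size, about the
#' vertical rotation axis through the volume centre (counter-clockwise viewed
#' from above; pixel centres at half-integers). Rows of the output maps run
#' along the vertical axis, columns along the detector.
#'
#' @param phantom a \linkS4class{VoxelPhantom}
#' @param angleDeg projection angle in degrees
#' @return a \linkS4class{ThicknessMaps} with one map per distinct material
#' @export
projectThickness <- function(phantom, angleDeg) {
  stopifnot(is(phantom, "VoxelPhantom"), is.finite(angleDeg))
  .projectMaterialVolume(.materialVolume(phantom), angleDeg,
                         phantom@voxelSize)
}

#' Synthetic flat-field pool
#'
#' Emulates a set of sample-free illumination images: one fixed per-pixel
#' gain map (detector response) plus a common low-frequency beam profile and
#' a small per-image illumination drift, as produced by beam fluctuations
#' between exposures. All fields are strictly positive and the generation is
#' reproducible for a fixed seed.
#'
#' @param n number of flat fields (>= 1)
#' @param field image size in pixels c(rows, cols)
#' @param structureAmplitude amplitude of the common low-frequency beam
#'   profile (relative; per-image drift is 20 percent of it)
#' @param gainDispersion standard deviation of the fixed per-pixel gain
#' @param pitch pixel pitch (m)
#' @param seed RNG seed
#' @return list of \linkS4class{FlatField}
#' @examples
#' flats <- makeFlatFields(5, field = c(64, 64), seed = 1)
#' @export
makeFlatFields <- function(n = 30L, field = c(256L, 256L),
                           structureAmplitude = 0.1, gainDispersion = 0.02,
                           pitch = 0.6e-6, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  nr <- as.integer(field[1]); nc <- as.integer(field[2])
  .withSeed(seed, {
    gain <- matrix(1 + gainDispersion * rnorm(nr * nc), nr, nc)
    gain <- pmax(gain, 0.1)
    base <- if (structureAmplitude > 0) .smoothField(nr, nc) else
      matrix(0, nr, nc)
    lapply(seq_len(n), function(i) {
      drift <- if (structureAmplitude > 0) .smoothField(nr, nc) else
        matrix(0, nr, nc)
      f <- (1 + structureAmplitude * base +
              0.2 * structureAmplitude * drift) * gain
      new("FlatField", data = pmax(f, 0.05), pitch = pitch)
    })
  })
}
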