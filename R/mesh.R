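#' @include segment.R
NULL

#' Export a label volume as a Wavefront OBJ mesh
#'
#' Writes one named group per region. Each region's surface is the set of
#' voxel boundary faces (faces between a region voxel and anything else),
#' which is closed (watertight) by construction; every quad face is split
#' into two triangles with outward orientation. Vertices sit on voxel
#' corners, in micrometres.
#'
#' @param labels a \linkS4class{LabelVolume} with at least one region
#' @param path output file path (.obj)
#' @return (invisibly) list with \code{vertices}, \code{triangles},
#'   \code{regions} and \code{path}
#' @export
exportMesh <- function(labels, path) {
  stopifnot(is(labels, "LabelVolume"))
  tab <- labels@table
  if (nrow(tab) == 0L) stop("no regions to export")
  lab <- labels@labels
  d <- dim(lab)
  scale <- labels@voxelSize * 1e6   # vertex coordinates in um
  nxc <- d[1] + 1L; nyc <- d[2] + 1L   # corner grid
  cornerId <- function(i, j, k) i + nxc * (j + nyc * k) + 1L  # 0-based corners

  lines <- character(0)
  allQuads <- list()
  groupOf <- integer(0)
  for (r in seq_len(nrow(tab))) {
    lv <- tab$label[r]
    idx <- which(lab == lv)
    k0 <- idx - 1L
    ix <- k0 %% d[1]
    iy <- (k0 %/% d[1]) %% d[2]
    iz <- k0 %/% (d[1] * d[2])
    inRegion <- array(FALSE, d)
    inRegion[idx] <- TRUE
    nb <- function(dx, dy, dz) {
      jx <- ix + dx; jy <- iy + dy; jz <- iz + dz
      inside <- jx >= 0 & jx < d[1] & jy >= 0 & jy < d[2] & jz >= 0 & jz < d[3]
      out <- logical(length(idx))
      out[inside] <- inRegion[1L + jx[inside] +
                                d[1] * (jy[inside] + d[2] * jz[inside])]
      out
    }
    quads <- list()
    # for each face direction: corner quadruple in outward-CCW order
    face <- function(sel, c1, c2, c3, c4) {
      if (!any(sel)) return(NULL)
      cbind(c1[sel], c2[sel], c3[sel], c4[sel])
    }
    x0 <- ix; x1 <- ix + 1L; y0 <- iy; y1 <- iy + 1L; z0 <- iz; z1 <- iz + 1L
    quads <- list(
      face(!nb(-1L, 0L, 0L), cornerId(x0, y0, z0), cornerId(x0, y0, z1),
           cornerId(x0, y1, z1), cornerId(x0, y1, z0)),
      face(!nb(1L, 0L, 0L), cornerId(x1, y0, z0), cornerId(x1, y1, z0),
           cornerId(x1, y1, z1), cornerId(x1, y0, z1)),
      face(!nb(0L, -1L, 0L), cornerId(x0, y0, z0), cornerId(x1, y0, z0),
           cornerId(x1, y0, z1), cornerId(x0, y0, z1)),
      face(!nb(0L, 1L, 0L), cornerId(x0, y1, z0), cornerId(x0, y1, z1),
           cornerId(x1, y1, z1), cornerId(x1, y1, z0)),
      face(!nb(0L, 0L, -1L), cornerId(x0, y0, z0), cornerId(x0, y1, z0),
           cornerId(x1, y1, z0), cornerId(x1, y0, z0)),
      face(!nb(0L, 0L, 1L), cornerId(x0, y0, z1), cornerId(x1, y0, z1),
           cornerId(x1, y1, z1), cornerId(x0, y1, z1)))
    q <- do.call(rbind, quads[!vapply(quads, is.null, logical(1))])
    allQuads[[r]] <- q
    groupOf <- c(groupOf, rep(r, nrow(q)))
  }
  quadMat <- do.call(rbind, allQuads)
  usedCorners <- sort(unique(as.vector(quadMat)))
  vid <- integer(max(usedCorners))
  vid[usedCorners] <- seq_along(usedCorners)

  c0 <- usedCorners - 1L
  cx <- (c0 %% nxc) * scale
  cy <- ((c0 %/% nxc) %% nyc) * scale
  cz <- (c0 %/% (nxc * nyc)) * scale
  vLines <- sprintf("v %.6g %.6g %.6g", cx, cy, cz)

  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# phaseCT label-volume surface mesh", con)
  writeLines(vLines, con)
  ntri <- 0L
  for (r in seq_len(nrow(tab))) {
    writeLines(sprintf("g region_%d", tab$label[r]), con)
    q <- allQuads[[r]]
    v1 <- vid[q[, 1]]; v2 <- vid[q[, 2]]; v3 <- vid[q[, 3]]; v4 <- vid[q[, 4]]
    writeLines(c(sprintf("f %d %d %d", v1, v2, v3),
                 sprintf("f %d %d %d", v1, v3, v4)), con)
    ntri <- ntri + 2L * nrow(q)
  }
  invisible(list(vertices = length(usedCorners), triangles = ntri,
                 regions = nrow(tab), path = path))
}
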