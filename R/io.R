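#' @include utils.R
NULL

.sidecarPath <- function(path) paste0(path, ".meta")

.writeSidecar <- function(path, meta) {
  keys <- names(meta)
  vals <- vapply(meta, function(v)
    paste(vapply(v, function(x)
      if (is.numeric(x)) sprintf("%.17g", x) else as.character(x),
      character(1)), collapse = ","), character(1))
  writeLines(paste0(keys, "=", vals), .sidecarPath(path))
}

.readSidecar <- function(path) {
  sc <- .sidecarPath(path)
  if (!file.exists(sc)) stop(sprintf("missing metadata sidecar '%s'", sc))
  lines <- readLines(sc)
  lines <- lines[nzchar(lines)]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) stop("malformed sidecar line (no key=value)")
  keys <- substr(lines, 1, eq - 1)
  vals <- substring(lines, eq + 1)
  stats::setNames(as.list(vals), keys)
}

## numeric (vector) metadata value
.metaNum <- function(meta, key) {
  if (is.null(meta[[key]])) stop(sprintf("missing sidecar key '%s'", key))
  as.numeric(strsplit(meta[[key]], ",", fixed = TRUE)[[1]])
}

#' Write an image stack as multi-page TIFF with a plain-text sidecar
#'
#' Frames are stored as 32-bit float TIFF pages, linearly mapped to [0, 1]
#' (the tiff format layer requires it); the affine mapping (offset, scale) is
#' recorded in the sidecar together with the frame geometry and any metadata
#' passed in, so that \code{\link{readStack}} restores the original values.
#' Output bytes are deterministic for identical input.
#'
#' @param frames 3D array (rows x cols x frames) or list of matrices
#' @param metadata named list of scalar/vector metadata (e.g. energy_kev,
#'   pitch_um, z_m, angles_deg, seed)
#' @param path output TIFF path; the sidecar goes to \code{<path>.meta}
#' @return (invisibly) the path
#' @export
writeStack <- function(frames, metadata = list(), path) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (!is.list(frames) || length(frames) == 0L)
    stop("frames must be a non-empty list or 3D array")
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) all(dim(f) == d), logical(1))))
    stop("all frames must share one shape")
  lo <- min(vapply(frames, min, numeric(1)))
  hi <- max(vapply(frames, max, numeric(1)))
  scale <- if (hi > lo) hi - lo else 1
  scaled <- lapply(frames, function(f) (f - lo) / scale)
  meta <- c(list(frames = length(frames), rows = d[1], cols = d[2],
                 offset = lo, scale = scale), metadata)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  .writeSidecar(path, meta)
  invisible(path)
}

#' Read an image stack written by \code{\link{writeStack}}
#'
#' @param path TIFF path with a \code{<path>.meta} sidecar
#' @param requiredKeys sidecar keys that must be present (error names the
#'   first missing one)
#' @return list with \code{frames} (3D array) and \code{metadata} (named list
#'   of character values; use numeric conversion as needed)
#' @export
readStack <- function(path, requiredKeys = character()) {
  if (!file.exists(path)) stop(sprintf("no such file '%s'", path))
  meta <- .readSidecar(path)
  for (k in c("frames", "rows", "cols", "offset", "scale", requiredKeys))
    if (is.null(meta[[k]]))
      stop(sprintf("missing sidecar key '%s' in '%s'", k, .sidecarPath(path)))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nf <- .metaNum(meta, "frames")
  d <- c(.metaNum(meta, "rows"), .metaNum(meta, "cols"))
  if (length(pages) != nf)
    stop(sprintf("format error: %d TIFF pages but sidecar says %d frames",
                 length(pages), nf))
  if (!all(dim(pages[[1]]) == d))
    stop("format error: TIFF page shape disagrees with sidecar")
  off <- .metaNum(meta, "offset")
  sc <- .metaNum(meta, "scale")
  arr <- array(0, c(d, nf))
  for (i in seq_len(nf)) arr[, , i] <- pages[[i]] * sc + off
  list(frames = arr, metadata = meta)
}

## ---------------------------------------------------------------------------
## Run configuration (INI-style sections of key=value, explicit units in keys)
## ---------------------------------------------------------------------------

.CONFIG_SPEC <- list(
  beamline = c(energy_kev = 12.7, z_m = 0.11, source_fwhm_v_um = 13,
               source_fwhm_h_um = 330, distance_m = 61,
               dcm_spread_urad = 0.7, dcm_distance_m = 45,
               flux_density_ph_s_mm2 = 1e13, exposure_s = 0.017),
  phantom = c(n_crystals = 20, size_min_um = 10, size_max_um = 50,
              slab_um = 150, slab_width_um = 500, voxel_um = 2.4, dim = 256),
  simulation = c(n_angles = 180, step_deg = 1, n_flats = 30, seed = 1),
  pipeline = c(delta_over_beta = 5e3, destripe_levels = 4,
               destripe_sigma = 2),
  segmentation = c(min_size = 27, smooth_sigma = 1, k = 5)
)

#' Default run configuration
#'
#' Named list of sections with every supported key and its default value;
#' units are explicit in the key names.
#'
#' @return nested named list
#' @export
defaultRunConfig <- function() lapply(.CONFIG_SPEC, as.list)

#' Read a run configuration file
#'
#' INI-style plain text: \code{[section]} headers and \code{key=value} lines;
#' \code{#} starts a comment. Unknown sections or keys are rejected; missing
#' ones take their defaults from \code{\link{defaultRunConfig}}.
#'
#' @param path configuration file path
#' @return nested named list like \code{\link{defaultRunConfig}}
#' @export
readRunConfig <- function(path) {
  cfg <- defaultRunConfig()
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!section %in% names(cfg))
        stop(sprintf("unknown config section '[%s]'", section))
      next
    }
    if (is.null(section)) stop("key=value before any [section]")
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop(sprintf("malformed config line '%s'", ln))
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substring(ln, eq + 1))
    if (!key %in% names(cfg[[section]]))
      stop(sprintf("unknown key '%s' in section '[%s]'", key, section))
    cfg[[section]][[key]] <- as.numeric(val)
  }
  cfg
}
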