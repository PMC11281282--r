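#' Read and write SHG images as TIFF
#'
#' Images are stored as single-page (2D) or multi-page (3D) 16-bit grayscale
#' TIFF. `writeShgTiff` rescales intensities to the 16-bit range and records
#' the physical pixel size, z-step and the intensity scale factor in a JSON
#' sidecar (`<path>.json`), which `readShgTiff` uses to restore the original
#' units; without a sidecar, intensities in \[0, 1\] are returned as read and
#' the pixel size must be supplied.
#'
#' @param path TIFF file path.
#' @param image an [ShgImage-class].
#' @param pixelSizeUm fallback pixel size when no sidecar is found.
#' @param zStepUm fallback z-step when no sidecar is found.
#' @return `readShgTiff` returns an [ShgImage-class]; `writeShgTiff` returns
#'   `path` invisibly.
#' @export
readShgTiff <- function(path, pixelSizeUm = 0.497, zStepUm = 3.0) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- if (length(pages) == 1L) {
    pages[[1]]
  } else {
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$intensity_scale)) arr <- arr * meta$intensity_scale
    if (!is.null(meta$pixel_size_um)) pixelSizeUm <- meta$pixel_size_um
    if (!is.null(meta$z_step_um)) zStepUm <- meta$z_step_um
  }
  ShgImage(arr, pixelSizeUm = pixelSizeUm, zStepUm = zStepUm)
}

#' @rdname readShgTiff
#' @export
writeShgTiff <- function(image, path) {
  stopifnot(is(image, "ShgImage"))
  x <- intensities(image)
  hi <- max(x, 1e-12)
  d <- dim(x)
  pages <- if (length(d) == 2L) {
    list(x / hi)
  } else {
    lapply(seq_len(d[3]), function(k) x[, , k] / hi)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(pixel_size_um = pixelSize(image), z_step_um = zStep(image),
         intensity_scale = hi),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write fiber masks as 8-bit TIFF
#'
#' Masks are written as 0/255 8-bit grayscale TIFF with a JSON sidecar
#' holding the pixel size; any strictly positive pixel reads back as fiber.
#'
#' @param path TIFF file path.
#' @param mask a [FiberMask-class].
#' @param pixelSizeUm fallback pixel size when no sidecar is found.
#' @return `readFiberMaskTiff` returns a [FiberMask-class];
#'   `writeFiberMaskTiff` returns `path` invisibly.
#' @export
readFiberMaskTiff <- function(path, pixelSizeUm = 0.497) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- if (length(pages) == 1L) {
    pages[[1]]
  } else {
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$pixel_size_um)) pixelSizeUm <- meta$pixel_size_um
  }
  FiberMask(arr > 0.5, pixelSizeUm = pixelSizeUm)
}

#' @rdname readFiberMaskTiff
#' @export
writeFiberMaskTiff <- function(mask, path) {
  stopifnot(is(mask, "FiberMask"))
  m <- maskArray(mask)
  d <- dim(m)
  pages <- if (length(d) == 2L) {
    list(m * 1)
  } else {
    lapply(seq_len(d[3]), function(k) m[, , k] * 1)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  jsonlite::write_json(list(pixel_size_um = pixelSize(mask)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-FOV and per-patient tables with a threshold sidecar
#'
#' Writes the standard CSVs of the quantification pipeline (per-FOV:
#' `patient_id, group, fov_id, percent_fiber_volume`; per-patient:
#' `patient_id, group, mean_volume, se, n_fov` plus any survival columns)
#' and a JSON sidecar recording the shape-filter thresholds and package
#' version, so the numbers always travel with the settings that produced
#' them.
#'
#' @param fovs per-FOV data.frame.
#' @param patients per-patient data.frame (e.g. from [patientAggregate()]).
#' @param dir output directory (created if needed).
#' @param shape a [ShapeFilterConfig-class] recorded in the sidecar.
#' @return invisibly, the paths written.
#' @export
writeCohortTables <- function(fovs, patients, dir,
                              shape = ShapeFilterConfig()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fovPath <- file.path(dir, "fov.csv")
  patPath <- file.path(dir, "patients.csv")
  utils::write.csv(fovs, fovPath, row.names = FALSE)
  utils::write.csv(patients, patPath, row.names = FALSE)
  meta <- list(
    min_length_um = shape@minLengthUm, max_width_um = shape@maxWidthUm,
    min_aspect = shape@minAspect, connectivity = shape@connectivity,
    package = "shgfiber",
    version = as.character(utils::packageVersion("shgfiber")))
  metaPath <- file.path(dir, "thresholds.json")
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA)
  invisible(c(fovPath, patPath, metaPath))
}

#' Read a tile layout from JSON
#'
#' The layout file is a JSON object with `pixel_size_um`, optionally
#' `overlap_um`, and `tiles`: a list of `{path, x_px, y_px}` entries whose
#' TIFF images are loaded relative to the layout file's directory.
#'
#' @param path layout JSON path.
#' @return a [TileLayout-class].
#' @export
readTileLayout <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  tiles <- lapply(seq_len(nrow(spec$tiles)), function(i) {
    p <- spec$tiles$path[i]
    if (!file.exists(p)) p <- file.path(base, spec$tiles$path[i])
    img <- readShgTiff(p, pixelSizeUm = spec$pixel_size_um)
    list(image = intensities(img),
         origin = c(spec$tiles$y_px[i], spec$tiles$x_px[i]))
  })
  TileLayout(tiles,
             pixelSizeUm = if (!is.null(spec$pixel_size_um))
               spec$pixel_size_um else 0.53,
             overlapUm = if (!is.null(spec$overlap_um))
               spec$overlap_um else 300)
}
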