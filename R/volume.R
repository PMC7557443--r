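#' Grayscale voxel volume with isotropic voxel size
#'
#' Light container for a reconstructed (or synthetic) micro-CT volume: a dense
#' 3D numeric array plus the isotropic voxel edge length in mm.  Axis order is
#' (depth, row, col); the depth axis is normal to the tooth wall in phantoms.
#'
#' @param voxels 3D numeric array of grayscale values.
#' @param voxel_size isotropic voxel edge length in mm (> 0).
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(voxels, voxel_size) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (any(dim(voxels) < 1L)) stop("`voxels` must be non-empty")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (mm)")
  structure(list(voxels = voxels, voxel_size = voxel_size),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume3d> %d x %d x %d voxels @ %.4g mm (%.3g x %.3g x %.3g mm)\n",
              d[1], d[2], d[3], x$voxel_size,
              d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary adhesive-layer mask
#'
#' @param mask 3D logical array (TRUE = adhesive voxel).
#' @param voxel_size isotropic voxel edge length in mm.
#' @return An object of class `adhesive_mask`.
#' @export
adhesive_mask <- function(mask, voxel_size) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array")
  if (!is.logical(mask)) {
    storage.mode(mask) <- "logical"
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (mm)")
  structure(list(mask = mask, voxel_size = voxel_size),
            class = "adhesive_mask")
}

#' @export
print.adhesive_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<adhesive_mask> %d x %d x %d voxels @ %.4g mm, %d foreground (%.1f%%)\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Dice overlap between two binary masks
#'
#' @param a,b `adhesive_mask` objects or 3D logical arrays of equal shape.
#' @return Dice coefficient 2|A∩B| / (|A|+|B|) in [0, 1].
#' @export
dice_overlap <- function(a, b) {
  ma <- if (inherits(a, "adhesive_mask")) a$mask else a
  mb <- if (inherits(b, "adhesive_mask")) b$mask else b
  if (!identical(dim(ma), dim(mb))) stop("mask shapes differ")
  2 * sum(ma & mb) / (sum(ma) + sum(mb))
}

#' Write / read a volume as a multi-page TIFF stack
#'
#' Pages run along the depth axis.  The voxel size is stored in a JSON sidecar
#' (`<path>.json`) because baseline TIFF tags cannot carry it portably;
#' `read_volume_tiff()` falls back to the `voxel_size` argument when no
#' sidecar is present.
#'
#' @param volume a `volume3d` (grayscale, written as 32-bit float) or an
#'   `adhesive_mask` (written as 8-bit).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  is_mask <- inherits(volume, "adhesive_mask")
  arr <- if (is_mask) volume$mask else volume$voxels
  d <- dim(arr)
  pages <- lapply(seq_len(d[1]), function(i)
    matrix(as.numeric(arr[i, , ]), d[2], d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = if (is_mask) 8L else 32L)
  meta <- list(voxel_size_mm = volume$voxel_size, dim = d,
               kind = if (is_mask) "mask" else "grayscale")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @param voxel_size voxel size in mm, used when no sidecar is found.
#' @param as_mask read back as an `adhesive_mask` (values > 0.5 foreground).
#' @export
read_volume_tiff <- function(path, voxel_size = NULL, as_mask = FALSE) {
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    voxel_size <- meta$voxel_size_mm
    if (!is.null(meta$kind)) as_mask <- identical(meta$kind, "mask")
  }
  if (is.null(voxel_size))
    stop("no JSON sidecar found; supply `voxel_size` explicitly")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  arr <- array(0, d)
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  if (as_mask) adhesive_mask(arr > 0.5, voxel_size)
  else volume3d(arr, voxel_size)
}
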