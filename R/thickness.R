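#' Local thickness transform (largest inscribed sphere)
#'
#' For every foreground voxel, the local thickness is the diameter of the
#' largest sphere that fits fully inside the voxelized layer (the union of
#' the foreground voxel cubes) while covering the voxel centre.  Sphere
#' centres are taken on the half-voxel grid and radii are exact Euclidean
#' distances to the complement, computed by an exact distance transform
#' followed by distance-ridge extraction and sphere marking.  This is the
#' standard wall-thickness definition used by micro-CT analysis software,
#' orientation-free by construction.
#'
#' With `boundary = "background"` everything beyond the grid is empty and
#' spheres are clipped at the domain hull; with `boundary = "solid"` the grid
#' is treated as a crop of a larger solid, which is the right convention for
#' phantom layers that run to the lateral edge of the volume.
#'
#' @param mask an [adhesive_mask()].
#' @param boundary `"background"` or `"solid"` (see above).
#' @return A `thickness_map`: list with `values` (3D array, mm; `NA` outside
#'   the mask) and `voxel_size`.
#' @export
local_thickness <- function(mask, boundary = c("background", "solid")) {
  stopifnot(inherits(mask, "adhesive_mask"))
  boundary <- match.arg(boundary)
  if (!any(mask$mask)) stop("empty mask")
  v <- cpp_local_thickness(as.logical(mask$mask), dim(mask$mask),
                           boundary == "background")
  structure(list(values = array(v * mask$voxel_size, dim(mask$mask)),
                 voxel_size = mask$voxel_size, boundary = boundary),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<thickness_map> %s voxels @ %.4g mm; defined on %d voxels, range [%.4g, %.4g] mm\n",
              paste(dim(x$values), collapse = " x "), x$voxel_size,
              length(v), min(v), max(v)))
  invisible(x)
}

#' Exhaustive-search local thickness (test oracle)
#'
#' Same geometric definition as [local_thickness()], computed by brute force:
#' for every candidate sphere centre the distance to the background is found
#' by direct minimization over all background voxel cubes, and every sphere
#' marks its covered voxels without any ridge reduction.  Definitionally
#' exact; guarded to masks of at most 64^3 voxels.
#'
#' @inheritParams local_thickness
#' @return A `thickness_map`.
#' @export
brute_force_thickness <- function(mask, boundary = c("background", "solid")) {
  stopifnot(inherits(mask, "adhesive_mask"))
  boundary <- match.arg(boundary)
  if (prod(dim(mask$mask)) > 64^3)
    stop("mask exceeds the 64^3 guard for exhaustive search")
  if (!any(mask$mask)) stop("empty mask")
  v <- cpp_brute_thickness(as.logical(mask$mask), dim(mask$mask),
                           boundary == "background")
  structure(list(values = array(v * mask$voxel_size, dim(mask$mask)),
                 voxel_size = mask$voxel_size, boundary = boundary),
            class = "thickness_map")
}

#' Widths measured in a virtual section plane
#'
#' Emulates the microscopy measurement on a sectioned sample: within one 2D
#' section of the mask the layer's centreline is traced per interface area
#' and the layer width (chord length through the mask, along the local
#' in-plane normal) is measured at `n_points` equally spaced centreline
#' points.  Unlike an operator's "characteristic points", the sampling is
#' deterministic and reproducible.
#'
#' @param mask an [adhesive_mask()].
#' @param plane_axis axis normal to the section plane (2 = row, 3 = col);
#'   the default row plane crosses all three interface areas.
#' @param plane_index 1-based index of the section along `plane_axis`.
#' @param n_points measurement points per interface area (default 10).
#' @param areas optional lateral factor matrix of area labels (as in
#'   `phantom_truth$areas`); when `NULL` the whole section is one area.
#' @return A data.frame of class `section_widths` with columns `area`,
#'   `point_index`, `width_mm`.
#' @export
virtual_section_widths <- function(mask, plane_axis = 2L, plane_index,
                                   n_points = 10L, areas = NULL) {
  stopifnot(inherits(mask, "adhesive_mask"))
  if (!plane_axis %in% c(2L, 3L)) stop("`plane_axis` must be 2 (row) or 3 (col)")
  d <- dim(mask$mask)
  if (plane_index < 1L || plane_index > d[plane_axis])
    stop("`plane_index` outside the grid")
  if (n_points < 1L) stop("`n_points` must be >= 1")
  h <- mask$voxel_size

  # 2D section: rows = depth, cols = the remaining lateral axis
  if (plane_axis == 2L) {
    sect <- mask$mask[, plane_index, ]
    lab <- if (is.null(areas)) NULL else areas[plane_index, ]
  } else {
    sect <- mask$mask[, , plane_index]
    lab <- if (is.null(areas)) NULL else areas[, plane_index]
  }
  if (!any(sect)) stop("section plane does not intersect the mask")
  nl <- ncol(sect)
  lab <- if (is.null(lab)) factor(rep("all", nl)) else factor(lab)

  # centre of the longest contiguous foreground run per in-plane column
  run_centre <- function(colv) {
    r <- rle(colv)
    if (!any(r$values)) return(c(NA_real_, NA_real_))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    fg <- which(r$values)
    k <- fg[which.max(r$lengths[fg])]
    c((starts[k] + ends[k]) / 2, r$lengths[k])
  }
  cen <- vapply(seq_len(nl), function(j) run_centre(sect[, j]), numeric(2))

  out <- list()
  for (a in levels(lab)) {
    cols <- which(lab == a & !is.na(cen[1, ]))
    if (length(cols) == 0L)
      stop("interface area '", a, "' is absent from this section")
    pick <- cols[unique(round(seq(1, length(cols), length.out = n_points)))]
    # pad by repetition if fewer distinct columns than points
    if (length(pick) < n_points)
      pick <- rep_len(pick, n_points)
    widths <- vapply(pick, function(j) {
      z0 <- cen[1, j]
      # local in-plane slope of the centreline (central difference, clamped)
      jm <- max(j - 1L, min(cols)); jp <- min(j + 1L, max(cols))
      zm <- cen[1, jm]; zp <- cen[1, jp]
      slope <- if (jp > jm && !is.na(zm) && !is.na(zp)) (zp - zm) / (jp - jm) else 0
      nvec <- c(1, -slope) / sqrt(1 + slope^2)  # (depth, lateral) normal
      step <- 0.25
      inside <- function(s) {
        z <- round(z0 + s * nvec[1]); y <- round(j + s * nvec[2])
        z >= 1 && z <= nrow(sect) && y >= 1 && y <= nl && sect[z, y]
      }
      up <- 0
      while (inside((up + 1) * step)) up <- up + 1
      dn <- 0
      while (inside(-(dn + 1) * step)) dn <- dn + 1
      (up + dn + 1) * step * h
    }, numeric(1))
    out[[a]] <- data.frame(area = a, point_index = seq_len(n_points),
                           width_mm = widths)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("section_widths", "data.frame")
  res
}
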