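#' Segmentation settings
#'
#' @param method `"auto"` for three-class Otsu thresholding (the adhesive is
#'   the middle intensity class) or `"band"` for an explicit intensity band.
#' @param band numeric `c(lo, hi)`, required when `method = "band"`.
#' @param opening apply a morphological opening (radius 1 voxel,
#'   6-neighbour structuring element) before component selection.
#' @param keep_largest retain only the largest 26-connected component.
#' @param fill_holes fill interior background cavities after component
#'   selection (isolated misclassified voxels inside the layer would clip
#'   the inscribed spheres of the thickness transform).
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(method = c("auto", "band"), band = NULL,
                       opening = TRUE, keep_largest = TRUE,
                       fill_holes = TRUE) {
  method <- match.arg(method)
  if (method == "band") {
    if (is.null(band) || length(band) != 2L || band[1] >= band[2])
      stop("`band` must be c(lo, hi) with lo < hi")
  }
  structure(list(method = method, band = band, opening = opening,
                 keep_largest = keep_largest, fill_holes = fill_holes),
            class = "seg_config")
}

#' Multi-level Otsu thresholds
#'
#' Exhaustive maximization of between-class variance over a histogram,
#' generalized to three classes (two thresholds).
#'
#' @param x numeric vector or array of intensities.
#' @param nbins histogram resolution.
#' @return Two thresholds splitting `x` into three classes.
#' @export
otsu_multilevel <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0)
    stop("segmentation failure: constant-intensity volume, no thresholds exist")
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  cnt <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins)
  p <- cnt / sum(cnt)
  cw <- cumsum(p)              # class cumulative weight
  cm <- cumsum(p * mids)       # class cumulative mean mass
  best <- -Inf; best_t <- c(NA, NA)
  # between-class variance for classes [1..i], (i..j], (j..nbins]
  for (i in 1:(nbins - 2L)) {
    w1 <- cw[i]
    if (w1 == 0) next
    m1 <- cm[i] / w1
    j <- (i + 1L):(nbins - 1L)
    w2 <- cw[j] - cw[i]
    w3 <- 1 - cw[j]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    m2 <- (cm[j] - cm[i]) / w2
    m3 <- (cm[nbins] - cm[j]) / w3
    mt <- cm[nbins]
    v <- w1 * (m1 - mt)^2 + w2 * (m2 - mt)^2 + w3 * (m3 - mt)^2
    v[!ok] <- -Inf
    k <- which.max(v)
    if (v[k] > best) {
      best <- v[k]
      best_t <- c(edges[i + 1L], edges[j[k] + 1L])
    }
  }
  if (!is.finite(best))
    stop("segmentation failure: histogram does not support three classes")
  best_t
}

# 3D binary erosion / dilation with the 6-neighbour cross structuring
# element.  The border is replicated (outside the grid behaves like the
# nearest in-grid voxel) so a layer that runs to the lateral domain edge is
# not eaten by the opening.
shift_replicate <- function(m, axis, by) {
  d <- dim(m)
  idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
  if (axis == 1L) m[idx, , , drop = FALSE]
  else if (axis == 2L) m[, idx, , drop = FALSE]
  else m[, , idx, drop = FALSE]
}

erode6 <- function(m) {
  out <- m
  for (ax in 1:3) {
    out <- out & shift_replicate(m, ax, 1L) & shift_replicate(m, ax, -1L)
  }
  out
}

dilate6 <- function(m) {
  out <- m
  for (ax in 1:3) {
    out <- out | shift_replicate(m, ax, 1L) | shift_replicate(m, ax, -1L)
  }
  out
}

open6 <- function(m) dilate6(erode6(m))

largest_component <- function(m) {
  lab <- cpp_label_components(as.logical(m), dim(m), 26L)
  if (all(lab == 0L)) return(array(FALSE, dim(m)))
  keep <- which.max(tabulate(lab))
  array(lab == keep, dim(m))
}

# Fill interior cavities: background components (6-connectivity, the
# complement of 26-connected foreground) that do not reach the grid border.
# Isolated misclassified voxels inside the layer would otherwise clip every
# inscribed sphere near them and bias the thickness field down.
fill_holes <- function(m) {
  bg <- !m
  lab <- array(cpp_label_components(as.logical(bg), dim(m), 6L), dim(m))
  d <- dim(m)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                     lab[, , c(1, d[3])]))
  border <- border[border > 0L]
  m | (bg & !array(lab %in% border, dim(m)))
}

#' Segment the adhesive layer from a grayscale volume
#'
#' Voxels in the adhesive intensity class are selected either by an explicit
#' band or by 3-class Otsu thresholding (middle class = adhesive, the three
#' materials being tooth, adhesive and composite).  The raw class mask is
#' cleaned by a radius-1 morphological opening and reduced to its largest
#' 26-connected component.
#'
#' @param volume a [volume3d()].
#' @param config a [seg_config()].
#' @return An [adhesive_mask()] with attribute `thresholds` = the intensity
#'   band actually used.
#' @export
segment_adhesive <- function(volume, config = seg_config()) {
  stopifnot(inherits(volume, "volume3d"))
  if (!inherits(config, "seg_config")) stop("`config` must be a seg_config()")
  if (config$method == "auto") {
    thr <- otsu_multilevel(volume$voxels)
    band <- c(thr[1], thr[2])
  } else {
    band <- config$band
  }
  m <- volume$voxels >= band[1] & volume$voxels <= band[2]
  if (config$method == "auto") {
    # Otsu band is half-open at the top threshold; include it explicitly
    m <- volume$voxels > band[1] & volume$voxels <= band[2]
  }
  if (!any(m))
    stop(sprintf("segmentation failure: no voxels in adhesive band [%.4g, %.4g]",
                 band[1], band[2]))
  if (config$opening) m <- open6(m)
  if (config$keep_largest) m <- largest_component(m)
  if (config$fill_holes) m <- fill_holes(m)
  if (!any(m))
    stop(sprintf(paste0("segmentation failure: empty mask after cleanup ",
                        "(band [%.4g, %.4g])"), band[1], band[2]))
  out <- adhesive_mask(m, volume$voxel_size)
  attr(out, "thresholds") <- band
  out
}
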