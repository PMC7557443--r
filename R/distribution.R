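#' Surface-area-versus-width distribution S(w)
#'
#' Builds the binned curve "area S of the interface surface whose adhesive
#' layer has local width w".  Interface faces are voxel faces between a mask
#' voxel and a non-mask voxel on the tooth side of the layer; each face
#' contributes `voxel_size^2` mm^2 to the bin containing the local thickness
#' of its mask voxel.  Face counting is exact, so the total area is conserved
#' under re-binning.
#'
#' @param mask an [adhesive_mask()].
#' @param tmap the matching `thickness_map` from [local_thickness()].
#' @param bin_width histogram bin width in mm (uniform, half-open bins
#'   `[e_i, e_{i+1})`); must be at least `voxel_size / 4`.
#' @param axis axis normal to the tooth wall (default 1 = depth).
#' @param side which side of the layer faces the tooth: `"low"` (smaller
#'   indices, the phantom convention) or `"high"`.
#' @return An object of class `sw_distribution`: `bin_edges` (length
#'   `nbins + 1`), `areas` (mm^2 per bin), `bin_width`, `voxel_size`, and
#'   `provenance` (face-counting convention).
#' @export
area_width_distribution <- function(mask, tmap, bin_width = 0.01,
                                    axis = 1L, side = c("low", "high")) {
  stopifnot(inherits(mask, "adhesive_mask"))
  side <- match.arg(side)
  h <- mask$voxel_size
  if (!is.null(tmap$voxel_size) && abs(tmap$voxel_size - h) > 1e-12)
    stop("mask and thickness map voxel sizes differ")
  if (bin_width < h / 4)
    stop(sprintf(paste0("configuration error: bin_width %.4g mm is below ",
                        "voxel_size / 4 = %.4g mm (meaningless resolution)"),
                 bin_width, h / 4))
  m <- mask$mask
  d <- dim(m)
  # neighbour toward the tooth: shift along `axis`; outside the grid counts
  # as non-mask, so a layer touching the grid face still exposes faces there
  shift_bg <- function(m, axis, by) {
    d <- dim(m)
    out <- array(FALSE, d)
    src <- seq_len(d[axis])
    keep <- src + by >= 1L & src + by <= d[axis]
    if (axis == 1L) out[src[keep], , ] <- m[src[keep] + by, , ]
    else if (axis == 2L) out[, src[keep], ] <- m[, src[keep] + by, ]
    else out[, , src[keep]] <- m[, , src[keep] + by]
    out
  }
  nb <- shift_bg(m, axis, if (side == "low") -1L else 1L)
  faces <- m & !nb
  tvals <- tmap$values[faces]
  if (any(is.na(tvals)))
    stop("thickness map is undefined on some interface faces")
  # bins are half-open [e_i, e_{i+1}) with centres on multiples of bin_width
  # (first edge at -bin_width/2), so a layer of constant thickness k*bin_width
  # sits exactly at a bin centre and the layer-cake volume is unbiased
  nbin <- max(1L, ceiling((max(tvals) + bin_width / 2) / bin_width + 1e-9))
  edges <- seq(-bin_width / 2, (nbin - 0.5) * bin_width, by = bin_width)
  idx <- pmin(findInterval(tvals, edges, rightmost.closed = FALSE), nbin)
  areas <- tabulate(idx, nbin) * h^2
  structure(list(bin_edges = edges, areas = areas, bin_width = bin_width,
                 voxel_size = h,
                 provenance = list(axis = axis, side = side,
                                   n_faces = sum(faces))),
            class = "sw_distribution")
}

#' @export
print.sw_distribution <- function(x, ...) {
  occ <- which(x$areas > 0)
  cat(sprintf("<sw_distribution> %d bins of %.4g mm; total area %.5g mm^2\n",
              length(x$areas), x$bin_width, sum(x$areas)))
  if (length(occ))
    cat(sprintf("  occupied widths %.4g-%.4g mm, peak %.5g mm^2 at %.4g mm\n",
                x$bin_edges[min(occ)], x$bin_edges[max(occ) + 1],
                max(x$areas), bin_centres(x)[which.max(x$areas)]))
  invisible(x)
}

#' @export
plot.sw_distribution <- function(x, model = NULL, ...) {
  wc <- bin_centres(x)
  graphics::plot(wc, x$areas, type = "h", lwd = 3, col = "grey55",
                 xlab = "width w (mm)", ylab = expression(S(w) ~ (mm^2)), ...)
  if (!is.null(model)) {
    ws <- seq(model$knots[1], model$knots[4], length.out = 400)
    graphics::lines(ws, evaluate_sw(model, ws), col = "firebrick", lwd = 2)
  }
  invisible(x)
}

bin_centres <- function(dist) {
  (dist$bin_edges[-1] + dist$bin_edges[-length(dist$bin_edges)]) / 2
}

#' Anchor points of an S(w) distribution
#'
#' Extracts the named points that parameterize the piecewise S(w) model:
#' onset (w0, S0), peak (wM, SM), tail knot (wI, SI) and terminal
#' (wmax, Sm).  The curve is first smoothed by a centred moving average; the
#' tail knot is the first bin centre after the peak where the magnitude of
#' the discrete gradient drops below 5% of the peak gradient magnitude of
#' the descending limb (the limb's own scale — the ascending limb is much
#' steeper and would otherwise dominate the threshold).
#'
#' @param dist an [area_width_distribution()].
#' @param smoothing_window centred moving-average window, bins (odd; 1 = no
#'   smoothing).
#' @param gradient_frac tail-knot threshold as a fraction of the descending
#'   limb's peak gradient magnitude.
#' @return An object of class `sw_anchors` with fields `w0, S0, wM, SM, wI,
#'   SI, wmax, Sm` (widths mm, areas mm^2).
#' @export
extract_anchors <- function(dist, smoothing_window = 3L,
                            gradient_frac = 0.05) {
  stopifnot(inherits(dist, "sw_distribution"))
  occ <- which(dist$areas > 0)
  if (length(occ) == 0L) stop("all-zero distribution")
  if (length(occ) < 6L)
    stop(sprintf("too few occupied bins (%d < 6) to extract anchors",
                 length(occ)))
  sw <- as.integer(smoothing_window)
  if (sw < 1L || sw %% 2L == 0L) stop("`smoothing_window` must be odd and >= 1")
  s <- if (sw == 1L) dist$areas else
    as.numeric(stats::filter(dist$areas, rep(1 / sw, sw), sides = 2))
  s[is.na(s)] <- dist$areas[is.na(s)]
  wc <- bin_centres(dist)

  i0 <- min(occ); imax <- max(occ)
  ipk <- which.max(s)
  if (ipk >= imax)
    stop("degenerate distribution: smoothed peak sits at the tail")
  grad <- c(NA, diff(s))                       # discrete gradient per bin
  post <- (ipk + 1L):imax
  gscale <- max(abs(grad[post]), na.rm = TRUE)
  if (gscale == 0) {
    iI <- post[1]
  } else {
    below <- post[!is.na(grad[post]) & abs(grad[post]) < gradient_frac * gscale]
    iI <- if (length(below)) below[1] else post[length(post)]
  }
  anchors <- structure(list(w0 = max(0, dist$bin_edges[i0]), S0 = s[i0],
                            wM = wc[ipk], SM = s[ipk],
                            wI = wc[iI], SI = s[iI],
                            wmax = dist$bin_edges[imax + 1L], Sm = s[imax]),
                       class = "sw_anchors")
  validate_anchors(anchors)
  anchors
}

#' Construct anchors directly
#'
#' @param w0,S0 onset width/area; @param wM,SM peak; @param wI,SI tail knot;
#'   @param wmax,Sm terminal.  Widths mm, areas mm^2.
#' @export
sw_anchors <- function(w0, S0, wM, SM, wI, SI, wmax, Sm) {
  a <- structure(list(w0 = w0, S0 = S0, wM = wM, SM = SM, wI = wI, SI = SI,
                      wmax = wmax, Sm = Sm), class = "sw_anchors")
  validate_anchors(a)
  a
}

validate_anchors <- function(a) {
  with(a, {
    if (!(w0 <= wM && wM < wI && wI < wmax))
      stop(sprintf("invalid anchors: need w0 <= wM < wI < wmax, got %.4g, %.4g, %.4g, %.4g",
                   w0, wM, wI, wmax))
    if (SI > SM + 1e-12) stop("invalid anchors: SI must not exceed SM")
    if (Sm < -1e-12 || S0 < -1e-12) stop("invalid anchors: areas must be >= 0")
  })
  invisible(a)
}

#' @export
print.sw_anchors <- function(x, ...) {
  cat(sprintf(paste0("<sw_anchors> onset (%.4g, %.5g)  peak (%.4g, %.5g)\n",
                     "             tail  (%.4g, %.5g)  end  (%.4g, %.5g)\n"),
              x$w0, x$S0, x$wM, x$SM, x$wI, x$SI, x$wmax, x$Sm))
  invisible(x)
}

#' Physical (thickness-weighted) layer volume from S(w)
#'
#' The volume of a layer whose area-at-thickness histogram is `dist`:
#' the sum over bins of area x bin-centre width.  This equals the layer-cake
#' integral of the survival curve (area with thickness >= w) and is the
#' bin-width-invariant physical volume statistic.
#'
#' @param dist an [area_width_distribution()].
#' @return Volume in mm^3.
#' @export
thickness_weighted_volume <- function(dist) {
  stopifnot(inherits(dist, "sw_distribution"))
  if (all(dist$areas == 0)) return(0)
  sum(dist$areas * bin_centres(dist))
}
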