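#' Piecewise linear/parabolic S(w) models
#'
#' Two template shapes describe the published S(w) curves.  Template A
#' (broad, late peak — conventional adhesives): three quadratics on
#' `[w0, (w0+wM)/2)`, `[(w0+wM)/2, wM)`, `[wM, wmax]`.  Template B (sharp
#' early peak — field-treated adhesives): quadratic `a*w^2` on `[0, wM)`,
#' quadratic on `[wM, wI)`, straight line on `[wI, wmax]`.  Pieces are stored
#' constant-first (`c0 + c1*w + c2*w^2`) and agree at interior knots (C0
#' continuity by construction; the published pieces are not
#' derivative-continuous, so no C1 constraint is imposed).
#'
#' @name sw_model
NULL

new_sw_model <- function(template, knots, pieces, anchors = NULL,
                         fitted = FALSE, fit_info = NULL) {
  stopifnot(template %in% c("A", "B"), length(knots) == 4L,
            length(pieces) == 3L)
  if (any(diff(knots) <= 0)) stop("model error: knots must be strictly increasing")
  m <- structure(list(template = template, knots = knots, pieces = pieces,
                      anchors = anchors, fitted = fitted,
                      fit_info = fit_info),
                 class = "sw_model")
  # C0 continuity at interior knots (tolerance 1e-9 mm^2)
  for (k in 2:3) {
    lhs <- poly_eval(pieces[[k - 1]], knots[k])
    rhs <- poly_eval(pieces[[k]], knots[k])
    if (abs(lhs - rhs) > 1e-9)
      stop(sprintf("model error: pieces disagree at knot %.4g (%.3g vs %.3g)",
                   knots[k], lhs, rhs))
  }
  m
}

poly_eval <- function(cf, w) cf[1] + cf[2] * w + cf[3] * w^2
poly_grad <- function(cf, w) cf[2] + 2 * cf[3] * w

#' @export
print.sw_model <- function(x, ...) {
  cat(sprintf("<sw_model> template %s%s, knots %s mm\n", x$template,
              if (x$fitted) " (least-squares fit)" else " (from anchors)",
              paste(signif(x$knots, 4), collapse = ", ")))
  nm <- c("f", "g", "h")
  for (i in 1:3) {
    cf <- x$pieces[[i]]
    cat(sprintf("  %s(w) = %.5g %+.5g w %+.5g w^2 on [%.4g, %.4g)\n", nm[i],
                cf[1], cf[2], cf[3], x$knots[i], x$knots[i + 1]))
  }
  if (!is.null(x$fit_info))
    cat(sprintf("  rss %.4g on %d bins%s\n", x$fit_info$rss, x$fit_info$n,
                if (any(x$fit_info$fallback))
                  paste0(" (fallback pieces: ",
                         paste(nm[x$fit_info$fallback], collapse = ","), ")")
                else ""))
  invisible(x)
}

model_knots <- function(anchors, template) {
  if (template == "A")
    c(anchors$w0, (anchors$w0 + anchors$wM) / 2, anchors$wM, anchors$wmax)
  else
    c(0, anchors$wM, anchors$wI, anchors$wmax)
}

#' Build a piecewise S(w) model through its anchor points
#'
#' Template A: the rise from onset to peak is split at the midpoint
#' `(w0+wM)/2`; `f` is the parabola with vertex at the onset reaching the
#' midpoint value `(S0+SM)/2`, `g` the parabola with vertex at the peak
#' through the same midpoint value, and `h` the quadratic interpolating
#' peak, tail knot and terminal.  Template B: `f = (SM/wM^2) w^2` from the
#' origin to the peak, `g` the parabola with vertex at the tail knot through
#' the peak, `h` the line from tail knot to terminal.  All pieces meet at
#' the knots (C0).
#'
#' @param anchors an [sw_anchors()].
#' @param template `"A"` or `"B"`.
#' @return An `sw_model`.
#' @export
build_model_from_anchors <- function(anchors, template = c("A", "B")) {
  template <- match.arg(template)
  validate_anchors(anchors)
  kn <- model_knots(anchors, template)
  if (any(diff(kn) <= 0))
    stop("model error: degenerate anchors give coincident knots")
  with(anchors, {
    if (template == "A") {
      mid <- (w0 + wM) / 2
      Smid <- (S0 + SM) / 2
      a <- (Smid - S0) / (mid - w0)^2
      # vertex form S0 + a (w - w0)^2, expanded constant-first
      f <- c(S0 + a * w0^2, -2 * a * w0, a)
      b <- (Smid - SM) / (mid - wM)^2
      g <- c(SM + b * wM^2, -2 * b * wM, b)
      h <- quad_through(c(wM, wI, wmax), c(SM, SI, Sm))
      new_sw_model("A", kn, list(f, g, h), anchors)
    } else {
      f <- c(0, 0, SM / wM^2)
      b <- (SM - SI) / (wM - wI)^2
      g <- c(SI + b * wI^2, -2 * b * wI, b)
      sl <- (Sm - SI) / (wmax - wI)
      h <- c(SI - sl * wI, sl, 0)
      new_sw_model("B", kn, list(f, g, h), anchors)
    }
  })
}

# quadratic through three points (Lagrange, returned constant-first)
quad_through <- function(w, S) {
  V <- cbind(1, w, w^2)
  as.numeric(solve(V, S))
}

#' Evaluate a piecewise S(w) model
#'
#' Pieces are half-open `[k_i, k_{i+1})`; the last interval includes `wmax`.
#'
#' @param model an `sw_model`.
#' @param w widths in mm, inside `[knots[1], knots[4]]`.
#' @return Areas in mm^2.
#' @export
evaluate_sw <- function(model, w) {
  idx <- piece_index(model, w)
  vapply(seq_along(w), function(i) poly_eval(model$pieces[[idx[i]]], w[i]),
         numeric(1))
}

#' @rdname evaluate_sw
#' @return `gradient_sw`: dS/dw in mm^2/mm.
#' @export
gradient_sw <- function(model, w) {
  idx <- piece_index(model, w)
  vapply(seq_along(w), function(i) poly_grad(model$pieces[[idx[i]]], w[i]),
         numeric(1))
}

piece_index <- function(model, w) {
  kn <- model$knots
  if (any(w < kn[1] - 1e-12 | w > kn[4] + 1e-12))
    stop(sprintf("domain error: w outside [%.4g, %.4g]", kn[1], kn[4]))
  pmin.int(pmax.int(findInterval(w, kn), 1L), 3L)
}

#' Fit a piecewise S(w) model to a binned distribution
#'
#' Constrained linear least squares: the template's polynomial pieces are fit
#' to the bin centres/areas of `dist` with equality constraints enforcing C0
#' continuity at the interior knots (knots come from the anchors and are not
#' optimized).  An interval with fewer than two bins is underdetermined;
#' its piece is taken from [build_model_from_anchors()] instead, held fixed,
#' and flagged in `fit_info$fallback`.
#'
#' @param dist an [area_width_distribution()].
#' @param template `"A"` or `"B"`.
#' @param anchors an [sw_anchors()] fixing the knots.
#' @return An `sw_model` with `fit_info` (rss, n, per-piece bin counts,
#'   fallback flags).
#' @export
fit_model <- function(dist, template = c("A", "B"), anchors) {
  template <- match.arg(template)
  stopifnot(inherits(dist, "sw_distribution"))
  anchor_model <- build_model_from_anchors(anchors, template)
  kn <- anchor_model$knots
  wc <- bin_centres(dist)
  keep <- wc >= kn[1] & wc <= kn[4]
  wc <- wc[keep]; y <- dist$areas[keep]
  pid <- pmin.int(pmax.int(findInterval(wc, kn), 1L), 3L)
  npar <- if (template == "A") c(3L, 3L, 3L) else c(3L, 3L, 2L)
  counts <- tabulate(pid[y > 0], 3L)   # occupied bins per piece interval
  fallback <- counts < 2L
  if (all(fallback)) return(anchor_model)

  # parameter layout: free pieces contribute their coefficients in order
  free <- which(!fallback)
  offs <- integer(3); p <- 0L
  for (i in free) { offs[i] <- p; p <- p + npar[i] }
  X <- matrix(0, length(wc), p)
  yy <- y
  for (i in seq_along(wc)) {
    pc <- pid[i]
    if (fallback[pc]) {
      yy[i] <- 0  # row dropped below
    } else {
      X[i, offs[pc] + seq_len(npar[pc])] <- wc[i]^(0:(npar[pc] - 1L))
    }
  }
  rows <- !fallback[pid]
  X <- X[rows, , drop = FALSE]; yy <- y[rows]

  # C0 constraints at interior knots: value(left piece) = value(right piece);
  # a fixed (fallback) side turns the constraint into an affine target
  C <- NULL; dvec <- NULL
  for (k in 2:3) {
    lp <- k - 1L; rp <- k
    row <- numeric(p); target <- 0
    if (!fallback[lp]) row[offs[lp] + seq_len(npar[lp])] <-
        kn[k]^(0:(npar[lp] - 1L))
    else target <- target + poly_eval(anchor_model$pieces[[lp]], kn[k])
    if (!fallback[rp]) row[offs[rp] + seq_len(npar[rp])] <-
        row[offs[rp] + seq_len(npar[rp])] - kn[k]^(0:(npar[rp] - 1L))
    else target <- target - poly_eval(anchor_model$pieces[[rp]], kn[k])
    if (any(row != 0)) { C <- rbind(C, row); dvec <- c(dvec, -target) }
  }

  # min ||y - X b||^2 s.t. C b = d, solved by null-space elimination
  # (numerically robust: the design entries span w^0..w^2 over small widths,
  # which makes the raw KKT system badly scaled)
  if (is.null(C)) {
    beta <- qr.solve(X, yy)
  } else {
    b0 <- t(C) %*% solve(tcrossprod(C), dvec)       # particular solution
    qrC <- qr(t(C))
    Nmat <- qr.Q(qrC, complete = TRUE)[, -seq_len(nrow(C)), drop = FALSE]
    gam <- qr.solve(X %*% Nmat, yy - X %*% b0)
    beta <- as.numeric(b0 + Nmat %*% gam)
  }
  pieces <- anchor_model$pieces
  for (i in free) {
    cf <- numeric(3)
    cf[seq_len(npar[i])] <- beta[offs[i] + seq_len(npar[i])]
    pieces[[i]] <- cf
  }
  resid <- yy - X %*% beta
  new_sw_model(template, kn, pieces, anchors, fitted = TRUE,
               fit_info = list(rss = sum(resid^2), n = length(yy),
                               bins_per_piece = counts, fallback = fallback))
}

#' Adhesive volume statistic V = integral of S(w) dw
#'
#' Exact piecewise antiderivative of the model over `[knots[1], wmax]` — a
#' closed form, not a quadrature estimate.
#'
#' @param model an `sw_model`.
#' @param group optional group label carried into the result.
#' @return An object of class `volume_stat`: `V` (mm^3), `group`,
#'   `template`, `knots`.
#' @export
integrate_model <- function(model, group = NULL) {
  stopifnot(inherits(model, "sw_model"))
  kn <- model$knots
  V <- 0
  for (i in 1:3) {
    cf <- model$pieces[[i]]
    anti <- function(w) cf[1] * w + cf[2] * w^2 / 2 + cf[3] * w^3 / 3
    V <- V + anti(kn[i + 1]) - anti(kn[i])
  }
  structure(list(V = V, group = group, template = model$template,
                 knots = kn), class = "volume_stat")
}

#' @export
print.volume_stat <- function(x, ...) {
  cat(sprintf("<volume_stat>%s V = %.6g mm^3 (template %s, [%.4g, %.4g] mm)\n",
              if (!is.null(x$group)) paste0(" group ", x$group) else "",
              x$V, x$template, x$knots[1], x$knots[4]))
  invisible(x)
}

#' Rank groups by adhesive volume
#'
#' @param volumes a list of `volume_stat` objects (or `sw_model`s, which are
#'   integrated on the fly), in group order; names are used as group labels
#'   when the statistics carry none.
#' @return A list with `table` (data.frame group/V sorted by decreasing V),
#'   `monotone_decreasing` (TRUE when V strictly decreases in the input
#'   order) and `ties` (TRUE when any two volumes coincide).
#' @export
compare_group_volumes <- function(volumes) {
  if (length(volumes) < 2L) stop("need at least two volumes to compare")
  vs <- lapply(seq_along(volumes), function(i) {
    v <- volumes[[i]]
    if (inherits(v, "sw_model")) v <- integrate_model(v)
    if (!inherits(v, "volume_stat")) stop("inputs must be volume_stat or sw_model")
    if (is.null(v$group))
      v$group <- if (!is.null(names(volumes)) && nzchar(names(volumes)[i]))
        names(volumes)[i] else as.character(i)
    v
  })
  V <- vapply(vs, `[[`, numeric(1), "V")
  grp <- vapply(vs, function(v) as.character(v$group), character(1))
  tab <- data.frame(group = grp, V = V)
  tab <- tab[order(-tab$V), ]
  rownames(tab) <- NULL
  list(table = tab,
       monotone_decreasing = all(diff(V) < 0),
       ties = anyDuplicated(V) > 0)
}
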