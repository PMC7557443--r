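# shared fixture builders (all generated in code; nothing on disk)

# random smooth blob mask: thresholded smoothed white noise
random_blob_mask <- function(n, seed, voxel_size = 0.01, frac = 0.4) {
  set.seed(seed)
  x <- array(rnorm(n^3), c(n, n, n))
  sm <- x
  for (ax in 1:3) {
    k <- rep(1 / 3, 3)
    sm <- (sm + aperm(apply(sm, setdiff(1:3, ax),
                            function(v) stats::filter(v, k, circular = TRUE)),
                      order(c(ax, setdiff(1:3, ax))))) / 2
  }
  m <- sm > stats::quantile(sm, 1 - frac)
  adhesive_mask(array(m, c(n, n, n)), voxel_size)
}

# axis-aligned slab of k voxels thickness inside an n^3 grid
slab_mask <- function(n, k, voxel_size = 0.01, from = NULL) {
  if (is.null(from)) from <- (n - k) %/% 2 + 1L
  m <- array(FALSE, c(n, n, n))
  m[from:(from + k - 1L), , ] <- TRUE
  adhesive_mask(m, voxel_size)
}

# synthetic sw_distribution sampled exactly from a piecewise model
dist_from_model <- function(model, bin_width, voxel_size = 0.001) {
  wmax <- model$knots[4]
  nbin <- ceiling((wmax + bin_width / 2) / bin_width + 1e-9)
  edges <- seq(-bin_width / 2, (nbin - 0.5) * bin_width, by = bin_width)
  cent <- (edges[-1] + edges[-length(edges)]) / 2
  inside <- cent >= model$knots[1] & cent <= wmax
  S <- numeric(nbin)
  S[inside] <- evaluate_sw(model, cent[inside])
  structure(list(bin_edges = edges, areas = pmax(S, 0),
                 bin_width = bin_width, voxel_size = voxel_size,
                 provenance = list(synthetic = TRUE)),
            class = "sw_distribution")
}

# anchors copied from the published Group 1 / Group 4 parameter sets
anchors_group1 <- function() {
  sw_anchors(w0 = 0, S0 = 0, wM = 0.07, SM = 0.014, wI = 0.2, SI = 0.008,
             wmax = 0.4, Sm = 0.002)
}
anchors_group4 <- function() {
  sw_anchors(w0 = 0, S0 = 0, wM = 0.015, SM = 0.015, wI = 0.18, SI = 0.002,
             wmax = 0.36, Sm = 0)
}

# random valid anchor set (for property sweeps); rejection-sampled so the
# requested template yields an admissible (nonnegative) S(w) curve
random_anchors <- function(seed, template = "B") {
  for (try in 0:50) {
    set.seed(seed + 100000L * try)
    wM <- runif(1, 0.02, 0.12)
    wI <- wM + runif(1, 0.03, 0.2)
    wmax <- wI + runif(1, 0.05, 0.25)
    SM <- runif(1, 0.005, 0.03)
    SI <- runif(1, 0.1, 0.8) * SM
    Sm <- runif(1, 0, 0.9) * SI
    S0 <- runif(1, 0, 0.3) * SM
    a <- sw_anchors(w0 = 0, S0 = S0, wM = wM, SM = SM, wI = wI, SI = SI,
                    wmax = wmax, Sm = Sm)
    m <- build_model_from_anchors(a, template)
    ws <- seq(m$knots[1], m$knots[4], length.out = 201)
    if (min(evaluate_sw(m, ws)) >= -1e-12) return(a)
  }
  stop("could not draw admissible anchors")
}

# independent rank-test oracles, written directly from the definitions:
# exhaustive enumeration over sign assignments / group assignments
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  m <- length(d)
  mu <- m * (m + 1) / 4
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  W <- signs %*% r
  mean(abs(W - mu) >= abs(obs - mu) - 1e-9)
}

enum_mann_whitney_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * length(y) / 2
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(N, n1)
  Us <- apply(idx, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  mean(abs(Us - mu) >= abs(obs - mu) - 1e-9)
}

# per-piece-scale coefficient error between two models: worst case, and the
# median over all coefficients (the summary used for noisy recovery, where a
# sparsely-binned interval can leave individual coefficients ill-determined)
coef_error <- function(fit, gen) {
  max(mapply(function(p, q) max(abs(p - q)) / max(abs(q)),
             fit$pieces, gen$pieces))
}
coef_error_median <- function(fit, gen) {
  e <- unlist(mapply(function(p, q) abs(p - q) / max(abs(q)),
                     fit$pieces, gen$pieces, SIMPLIFY = FALSE))
  median(e)
}

# quadrature reference for a piecewise model: adaptive quadrature on each
# smooth polynomial piece, summed (integrate() cannot reach 1e-10 across the
# knot discontinuities in the derivative)
quadrature_V <- function(m) {
  sum(vapply(1:3, function(i)
    integrate(function(w) evaluate_sw(m, pmin(w, m$knots[4])),
              m$knots[i], m$knots[i + 1],
              rel.tol = 1e-13, subdivisions = 500L)$value, numeric(1)))
}
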