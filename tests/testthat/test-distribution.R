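slab_dist <- function(k = 10L, n = 32L, h = 0.01, bw = 0.01) {
  m <- slab_mask(n, k, voxel_size = h)
  tm <- local_thickness(m, "solid")
  list(mask = m, tmap = tm,
       dist = area_width_distribution(m, tm, bw))
}

test_that("constant slab gives a delta distribution carrying the full area", {
  sd <- slab_dist()
  d <- sd$dist
  occ <- which(d$areas > 0)
  expect_length(occ, 1L)
  expect_equal(bin_centre <- (d$bin_edges[occ] + d$bin_edges[occ + 1]) / 2, 0.10)
  expect_equal(d$areas[occ], 32^2 * 0.01^2)  # whole lateral face area
})

test_that("total area is conserved exactly and under re-binning", {
  m <- random_blob_mask(20, seed = 9)
  tm <- local_thickness(m, "background")
  d1 <- area_width_distribution(m, tm, 0.01)
  d2 <- area_width_distribution(m, tm, 0.005)
  expect_identical(sum(d1$areas), d1$provenance$n_faces * m$voxel_size^2)
  expect_identical(sum(d1$areas), sum(d2$areas))
})

test_that("two-plateau layer splits its area evenly between two bins", {
  # two full-lateral slabs stacked in depth: no lateral cliffs, so each wall
  # reads exactly its own width and the interface area splits evenly
  n <- 32L; h <- 0.01
  m <- array(FALSE, c(n, n, n))
  m[5:9, , ] <- TRUE     # 5 voxels = 0.05 mm
  m[20:29, , ] <- TRUE   # 10 voxels = 0.10 mm
  msk <- adhesive_mask(m, h)
  tm <- local_thickness(msk, "solid")
  d <- area_width_distribution(msk, tm, 0.01)
  occ <- which(d$areas > 0.01 * sum(d$areas))
  expect_length(occ, 2L)
  expect_lt(abs(d$areas[occ[1]] - d$areas[occ[2]]) / max(d$areas[occ]), 0.02)
  # thickness-weighted volume recovers the constructed truth
  vtrue <- (5 + 10) * 32 * 32 * h^3
  expect_lt(abs(thickness_weighted_volume(d) - vtrue) / vtrue, 0.05)
})

test_that("bin width below a quarter voxel is rejected", {
  sd <- slab_dist()
  expect_error(area_width_distribution(sd$mask, sd$tmap, 0.002),
               "configuration error")
})

test_that("anchors are recovered from a model-generated distribution", {
  gen <- build_model_from_anchors(anchors_group4(), "B")
  d <- dist_from_model(gen, 0.005)
  a <- extract_anchors(d, smoothing_window = 1L)
  expect_lte(abs(a$wM - 0.015), 0.005)         # within one bin
  expect_lte(abs(a$SM - 0.015) / 0.015, 0.05)  # within 5% in S
  expect_lte(abs(a$wI - 0.18), 0.006)          # within one bin of the knot
  expect_equal(a$wmax, 0.3575, tolerance = 0.006)
  expect_lte(a$Sm, 0.05 * a$SM)
})

test_that("unimodal histogram peaks where it should; monotone case stays valid", {
  bw <- 0.01
  edges <- seq(-bw / 2, 0.195, by = bw)
  peaked <- c(0, 1, 2, 5, 9, 5, 2, 1, 1, 1, 1, 0.5, 0.5, 0.2, 0.2, 0.1, 0.1, 0.1, 0, 0) / 100
  d <- structure(list(bin_edges = edges, areas = peaked, bin_width = bw,
                      voxel_size = 0.001, provenance = list()),
                 class = "sw_distribution")
  a <- extract_anchors(d, smoothing_window = 1L)
  expect_equal(a$wM, 0.04)
  mono <- d
  mono$areas <- rev(sort(peaked))
  am <- extract_anchors(mono, smoothing_window = 1L)
  expect_equal(am$wM, 0)           # first occupied bin centre
  expect_true(am$w0 <= am$wM && am$wM < am$wI && am$wI < am$wmax)
})

test_that("degenerate distributions are rejected", {
  bw <- 0.01
  edges <- seq(-bw / 2, 0.095, by = bw)
  zero <- structure(list(bin_edges = edges, areas = numeric(10), bin_width = bw,
                         voxel_size = 0.001, provenance = list()),
                    class = "sw_distribution")
  expect_error(extract_anchors(zero), "all-zero")
  few <- zero; few$areas[3:5] <- 1
  expect_error(extract_anchors(few), "too few occupied bins")
  expect_identical(thickness_weighted_volume(zero), 0)
})

test_that("thickness-weighted volume is stable under re-binning", {
  sp <- phantom_spec(grid_shape = c(64, 48, 48), voxel_size = 0.005, seed = 6)
  ph <- generate_phantom(sp)
  m <- adhesive_mask(ph$truth$mask, 0.005)
  tm <- local_thickness(m, "solid")
  d1 <- area_width_distribution(m, tm, 0.01)
  d2 <- area_width_distribution(m, tm, 0.0025)
  expect_lte(abs(thickness_weighted_volume(d1) - thickness_weighted_volume(d2)),
             2 * 0.01 * sum(d1$areas))
})

test_that("preset S(w) peaks sit in the published order and windows", {
  wM <- vapply(1:4, function(g) {
    vals <- vapply(1:2, function(s) {
      sp <- group_preset(g, seed = s)
      ph <- generate_phantom(sp)
      m <- adhesive_mask(ph$truth$mask, sp$voxel_size)
      tm <- local_thickness(m, "solid")
      d <- area_width_distribution(m, tm, attr(sp, "suggested_bin_width"))
      extract_anchors(d)$wM
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(wM) < 0))  # peaks shift left from Group 1 to 4
  expect_gte(wM[1], 0.07); expect_lte(wM[1], 0.13)
  expect_gte(wM[2], 0.05); expect_lte(wM[2], 0.11)
  expect_gte(wM[3], 0.015); expect_lte(wM[3], 0.035)
  expect_gte(wM[4], 0.008); expect_lte(wM[4], 0.028)
})
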