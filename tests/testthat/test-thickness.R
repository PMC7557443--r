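test_that("slab thickness equals the exact layer width for even and odd k", {
  for (k in c(9L, 10L)) {
    m <- slab_mask(24, k, voxel_size = 0.01)
    tm <- local_thickness(m, "solid")
    expect_equal(unique(tm$values[m$mask]), k * 0.01)
    # with a background boundary the slab interior (away from the lateral
    # hull) still reads the full width
    tb <- local_thickness(m, "background")
    expect_equal(tb$values[12, 12, 12], k * 0.01)
  }
})

test_that("single voxel and small cube follow the inscribed-sphere closed forms", {
  m1 <- array(FALSE, c(7, 7, 7)); m1[4, 4, 4] <- TRUE
  t1 <- local_thickness(adhesive_mask(m1, 0.01), "background")
  expect_equal(t1$values[4, 4, 4], 0.01)
  m2 <- array(FALSE, c(8, 8, 8)); m2[4:5, 4:5, 4:5] <- TRUE
  t2 <- local_thickness(adhesive_mask(m2, 0.01), "background")
  expect_equal(unique(t2$values[m2]), 0.02)
})

test_that("voxelized ball reaches its diameter up to surface voxelization", {
  n <- 24; cc <- 12.5; r <- 8; h <- 0.01
  g <- expand.grid(1:n, 1:n, 1:n)
  m <- array(sqrt((g[, 1] - cc)^2 + (g[, 2] - cc)^2 + (g[, 3] - cc)^2) <= r,
             c(n, n, n))
  tm <- local_thickness(adhesive_mask(m, h), "background")
  mx <- max(tm$values, na.rm = TRUE)
  # the inscribed sphere is tangent to the stair-stepped surface cubes, so
  # it can fall short of the continuous diameter by a voxel or two
  expect_lte(mx, 2 * r * h + h)
  expect_gte(mx, 2 * r * h - 2 * h)
})

test_that("fast transform equals the exhaustive oracle on random masks", {
  for (s in 1:6) {
    n <- sample(14:20, 1)
    m <- random_blob_mask(n, seed = 100 + s)
    for (b in c("background", "solid")) {
      f <- local_thickness(m, b)
      o <- brute_force_thickness(m, b)
      expect_identical(f$values, o$values,
                       label = sprintf("seed %d boundary %s", s, b))
    }
  }
})

test_that("oracle guard and empty masks raise errors", {
  big <- adhesive_mask(array(TRUE, c(70, 70, 70)), 0.01)
  expect_error(brute_force_thickness(big), "guard")
  empty <- adhesive_mask(array(FALSE, c(8, 8, 8)), 0.01)
  expect_error(local_thickness(empty), "empty mask")
})

test_that("median thickness recovers the generating constant width", {
  for (t in c(0.02, 0.05, 0.1, 0.2)) {
    sp <- phantom_spec(grid_shape = c(64, 32, 32), voxel_size = 0.005,
                       base_thickness = t, variation_amplitude = 0,
                       noise_sigma = 0, seed = 1)
    ph <- generate_phantom(sp)
    tm <- local_thickness(adhesive_mask(ph$truth$mask, 0.005), "solid")
    expect_lte(abs(median(tm$values[ph$truth$mask]) - t), 0.005)
  }
})

test_that("virtual section widths match a constant slab and are plane-invariant", {
  sp <- phantom_spec(grid_shape = c(48, 32, 32), voxel_size = 0.01,
                     base_thickness = 0.1, variation_amplitude = 0,
                     noise_sigma = 0, seed = 1)
  ph <- generate_phantom(sp)
  m <- adhesive_mask(ph$truth$mask, 0.01)
  w1 <- virtual_section_widths(m, 2L, 10L, 10L, ph$truth$areas)
  expect_identical(nrow(w1), 30L)  # 10 points x 3 areas
  expect_true(all(abs(w1$width_mm - 0.1) <= 0.01))
  w2 <- virtual_section_widths(m, 2L, 20L, 10L, ph$truth$areas)
  expect_true(all(abs(w1$width_mm - w2$width_mm) <= 0.01))
})

test_that("section widths are consistent with the thickness map", {
  sp <- phantom_spec(grid_shape = c(64, 48, 48), voxel_size = 0.005,
                     base_thickness = 0.08, variation_amplitude = 0.03,
                     correlation_length = 0.1, noise_sigma = 0, seed = 4)
  ph <- generate_phantom(sp)
  m <- adhesive_mask(ph$truth$mask, 0.005)
  tm <- local_thickness(m, "solid")
  plane <- 24L
  w <- virtual_section_widths(m, 2L, plane, 10L, ph$truth$areas)
  sect_vals <- tm$values[, plane, ]
  rng <- range(sect_vals, na.rm = TRUE)
  expect_gte(mean(w$width_mm), rng[1] - 0.005)
  expect_lte(mean(w$width_mm), rng[2] + 0.005)
  # section range sits inside the map range up to one voxel
  expect_gte(min(w$width_mm), rng[1] - 0.005)
  expect_lte(max(w$width_mm), rng[2] + 0.005)
})

test_that("section plane outside the layer raises an error", {
  m <- slab_mask(24, 6, voxel_size = 0.01)
  mm <- m$mask
  mm[, 1:4, ] <- FALSE  # carve the layer away from the first rows
  expect_error(virtual_section_widths(adhesive_mask(mm, 0.01), 2L, 2L, 5L),
               "does not intersect")
  expect_error(virtual_section_widths(m, 2L, 300L, 5L), "outside the grid")
})
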