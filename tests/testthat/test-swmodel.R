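test_that("anchor construction reproduces published closed-form pieces", {
  # sharp-peak template with the Group 4 parameter set: leading coefficient
  # of the rise is SM / wM^2 = 0.015 / 0.015^2 = 66.67
  m4 <- build_model_from_anchors(anchors_group4(), "B")
  expect_equal(m4$pieces[[1]][3], 66.67, tolerance = 0.01 / 66.67)
  expect_identical(m4$pieces[[1]][1:2], c(0, 0))
  # terminal interpolation: Sm = 0 makes the tail line vanish at wmax
  expect_equal(poly_val <- m4$pieces[[3]][1] + m4$pieces[[3]][2] * 0.36, 0)
  # broad-peak template with the Group 1 parameter set reproduces the
  # published descending parabola g(w) = -5.714 w^2 + 0.8 w - 0.014
  m1 <- build_model_from_anchors(anchors_group1(), "A")
  expect_equal(m1$pieces[[2]], c(-0.014, 0.8, -5.714286), tolerance = 1e-6)
})

test_that("constructed models are continuous and nonnegative on their domain", {
  for (s in 1:20) {
    for (tpl in c("A", "B")) {
      a <- random_anchors(s, tpl)
      m <- build_model_from_anchors(a, tpl)
      for (k in 2:3) {
        below <- evaluate_sw(m, m$knots[k] - 1e-9)
        above <- evaluate_sw(m, m$knots[k])
        expect_lt(abs(below - above), 1e-6,
                  label = sprintf("seed %d template %s knot %d", s, tpl, k))
      }
      ws <- seq(m$knots[1], m$knots[4], length.out = 101)
      expect_true(all(evaluate_sw(m, ws) >= -1e-9))
    }
  }
})

test_that("degenerate anchors are rejected", {
  expect_error(sw_anchors(0, 0, 0.1, 0.01, 0.1, 0.005, 0.3, 0),
               "invalid anchors")
  a <- anchors_group4()
  a$wM <- 0  # knots 0 and wM coincide for template B
  expect_error(build_model_from_anchors(a, "B"), "model error|invalid")
})

test_that("gradient of the published descending piece matches its printed form", {
  m1 <- build_model_from_anchors(anchors_group1(), "A")
  ws <- seq(0.035, 0.0699, length.out = 100)
  expect_lt(max(abs(gradient_sw(m1, ws) - (-11.428 * ws + 0.8))), 1e-4)
  # a linear tail piece has constant gradient
  m4 <- build_model_from_anchors(anchors_group4(), "B")
  expect_equal(diff(gradient_sw(m4, c(0.2, 0.3))), 0)
  expect_error(evaluate_sw(m4, 0.5), "domain error")
  expect_error(gradient_sw(m4, -0.01), "domain error")
})

test_that("closed-form integral matches adaptive quadrature and closed forms", {
  # f = a w^2 on [0, L] integrates to a L^3 / 3
  aB <- sw_anchors(w0 = 0, S0 = 0, wM = 0.1, SM = 0.04, wI = 0.2, SI = 0.016,
                   wmax = 0.3, Sm = 0.01)
  mB <- build_model_from_anchors(aB, "B")
  expect_equal(integrate_model_piece <- with(mB, {
    cf <- pieces[[1]]
    cf[3] * knots[2]^3 / 3
  }), 0.04 / 0.1^2 * 0.1^3 / 3)
  for (s in 1:30) {
    for (tpl in c("A", "B")) {
      a <- random_anchors(300 + s, tpl)
      m <- build_model_from_anchors(a, tpl)
      V <- integrate_model(m)$V
      expect_lt(abs(V - quadrature_V(m)) / max(abs(V), 1e-12), 1e-10)
    }
  }
})

test_that("integral is additive over the knot partition and linear in S", {
  a <- anchors_group1()
  m <- build_model_from_anchors(a, "A")
  by_piece <- vapply(1:3, function(i) {
    cf <- m$pieces[[i]]
    anti <- function(w) cf[1] * w + cf[2] * w^2 / 2 + cf[3] * w^3 / 3
    anti(m$knots[i + 1]) - anti(m$knots[i])
  }, numeric(1))
  expect_equal(sum(by_piece), integrate_model(m)$V)
  a2 <- a
  for (f in c("S0", "SM", "SI", "Sm")) a2[[f]] <- 2 * a[[f]]
  m2 <- build_model_from_anchors(a2, "A")
  expect_equal(integrate_model(m2)$V, 2 * integrate_model(m)$V)
})

test_that("least-squares fit recovers generating coefficients exactly without noise", {
  for (tpl in c("A", "B")) {
    a <- if (tpl == "A") anchors_group1() else anchors_group4()
    gen <- build_model_from_anchors(a, tpl)
    d <- dist_from_model(gen, 0.005)
    fit <- fit_model(d, tpl, a)
    expect_lt(coef_error(fit, gen), 1e-6)
    expect_false(any(fit$fit_info$fallback))
  }
})

test_that("fit stays accurate under measurement noise", {
  a <- anchors_group1()
  gen <- build_model_from_anchors(a, "A")
  d0 <- dist_from_model(gen, 0.01)
  errs <- vapply(1:10, function(s) {
    set.seed(s)
    d <- d0
    on <- d$areas > 0
    d$areas[on] <- pmax(d$areas[on] + rnorm(sum(on), sd = 0.02 * a$SM), 0)
    coef_error_median(fit_model(d, "A", a), gen)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("underdetermined intervals fall back to the anchor construction", {
  a <- anchors_group4()
  gen <- build_model_from_anchors(a, "B")
  d <- dist_from_model(gen, 0.01)
  cent <- (d$bin_edges[-1] + d$bin_edges[-length(d$bin_edges)]) / 2
  d$areas[cent < a$wM] <- 0  # starve the rise interval
  d$areas[cent == 0.01] <- gen$pieces[[1]][3] * 0.01^2  # leave a single bin
  fit <- fit_model(d, "B", a)
  expect_true(fit$fit_info$fallback[1])
  expect_identical(fit$pieces[[1]], gen$pieces[[1]])
  # continuity still holds against the fixed piece
  expect_lt(abs(evaluate_sw(fit, a$wM - 1e-12) - evaluate_sw(fit, a$wM)), 1e-9)
})

test_that("group volume comparison reports ordering, ties and scaling", {
  a <- anchors_group1()
  m <- build_model_from_anchors(a, "A")
  a2 <- a
  for (f in c("S0", "SM", "SI", "Sm")) a2[[f]] <- a[[f]] / 2
  m2 <- build_model_from_anchors(a2, "A")
  cmp <- compare_group_volumes(list(g1 = m, g2 = m2))
  expect_true(cmp$monotone_decreasing)
  expect_false(cmp$ties)
  expect_equal(cmp$table$V[1] / cmp$table$V[2], 2)
  tie <- compare_group_volumes(list(m, m))
  expect_false(tie$monotone_decreasing)
  expect_true(tie$ties)
})
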