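test_that("width ranges and summaries follow the packaged table", {
  t1 <- load_table1_fixture()
  expect_equal(unname(width_range(t1, 4, "micro-CT")), c(0.011, 0.032))
  expect_equal(unname(width_range(t1, 1, "microscopy")), c(0.021, 0.29))
  one <- t1[1, , drop = FALSE]
  expect_equal(unname(width_range(one, one$group, one$method)),
               rep(one$width_mm, 2))
  expect_error(width_range(t1, 9, "micro-CT"), "no records")
  s <- summarize_widths(t1, method = "micro-CT", area = "vestibular", group = 4)
  expect_identical(s$n, 5L)
  expect_equal(s$mean, (0.017 + 0.021 + 0.030 + 0.021 + 0.014) / 5)
  const <- data.frame(group = 1, area = "oral", method = "m",
                      width_mm = rep(0.02, 4))
  sc <- summarize_widths(const)
  expect_equal(sc$sd, 0)
  expect_equal(sc$min, sc$max)
  expect_error(summarize_widths(t1, area = "nowhere"), "insufficient")
})

test_that("signed-rank test handles identical pairs and pure-positive shifts", {
  x <- c(1, 2, 3, 4, 5, 6)
  r0 <- wilcoxon_signed_rank(x, x)
  expect_equal(r0$p_value, 1)
  expect_false(r0$significant)
  rp <- wilcoxon_signed_rank(x, x + 1)
  expect_identical(rp$ranks$n[rp$ranks$ranks == "negative"], 0L)
  expect_equal(rp$ranks$sum_ranks[rp$ranks$ranks == "positive"], 21)  # 6*7/2
})

test_that("signed-rank p-values agree with exhaustive enumeration", {
  set.seed(21)
  for (i in 1:8) {
    n <- sample(6:10, 1)
    x <- round(rnorm(n), 1)
    y <- round(x + rnorm(n, 0.4, 0.6), 1)
    keep <- (y - x) != 0
    if (sum(keep) < 5) next
    res <- wilcoxon_signed_rank(x, y)
    expect_equal(res$p_value, enum_signed_rank_p(y[keep] - x[keep]),
                 tolerance = 1e-12, label = paste("case", i))
  }
})

test_that("rank sums are conserved and the asymptotic branch matches wilcox.test", {
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(30); y <- x + rnorm(30, 0.2)
    res <- wilcoxon_signed_rank(x, y)
    m <- res$n_nonzero
    expect_equal(sum(res$ranks$sum_ranks), m * (m + 1) / 2)
    ref <- suppressWarnings(stats::wilcox.test(y, x, paired = TRUE,
                                               exact = FALSE, correct = FALSE))
    expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney handles symmetry, separation and matches wilcox.test", {
  ident <- mann_whitney_u(rep(2, 5), rep(2, 6))
  expect_equal(ident$U1, 5 * 6 / 2)
  expect_equal(ident$p_value, 1)
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  set.seed(41)
  x <- rnorm(30); y <- rnorm(30, 0.5)
  res <- mann_whitney_u(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = FALSE))
  expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(sum(res$ranks$sum_ranks), 60 * 61 / 2)
})

test_that("Mann-Whitney p-values agree with exhaustive enumeration", {
  set.seed(51)
  for (i in 1:10) {
    x <- round(rnorm(5), 1)
    y <- round(rnorm(5, 0.5), 1)
    res <- mann_whitney_u(x, y)
    expect_equal(res$p_value, enum_mann_whitney_p(x, y), tolerance = 1e-12,
                 label = paste("draw", i))
  }
})

test_that("exact and asymptotic p-values stay close for moderate samples", {
  set.seed(61)
  for (i in 1:6) {
    # pooled n = 16: package asymptotic vs test-side full enumeration
    x <- rnorm(8); y <- rnorm(8, 0.3)
    asym <- mann_whitney_u(x, y, exact_limit = 0L)
    expect_lt(abs(asym$p_value - enum_mann_whitney_p(x, y)), 0.05)
    d <- rnorm(12)
    e2 <- wilcoxon_signed_rank(numeric(12), d, exact_limit = 12L)
    a2 <- wilcoxon_signed_rank(numeric(12), d, exact_limit = 0L)
    expect_lt(abs(e2$p_value - a2$p_value), 0.05)
  }
})
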