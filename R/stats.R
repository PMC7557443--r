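#' Width range for a group and measurement method
#'
#' @param records width records as returned by [load_table1_fixture()]
#'   (columns `group`, `method`, `width_mm`; extra columns ignored).
#' @param group group id to select.
#' @param method measurement method to select (`"micro-CT"` or
#'   `"microscopy"`).
#' @return `c(min, max)` width in mm over all areas and samples.
#' @export
width_range <- function(records, group, method) {
  w <- records$width_mm[records$group == group & records$method == method]
  if (length(w) < 1L)
    stop(sprintf("no records for group %s / method '%s'", group, method))
  c(min = min(w), max = max(w))
}

#' Summary statistics of selected width records
#'
#' Standard n / mean / SD (n-1 denominator) / min / max summary in the layout
#' of the published per-area comparison table.
#'
#' @param records width records (columns `group`, `area`, `method`,
#'   `width_mm`).
#' @param method,area,group optional selectors; `NULL` selects all.
#' @return A one-row data.frame with `n`, `mean`, `sd`, `min`, `max` (mm).
#' @export
summarize_widths <- function(records, method = NULL, area = NULL,
                             group = NULL) {
  sel <- rep(TRUE, nrow(records))
  if (!is.null(method)) sel <- sel & records$method == method
  if (!is.null(area)) sel <- sel & records$area == area
  if (!is.null(group)) sel <- sel & records$group == group
  w <- records$width_mm[sel]
  if (length(w) < 2L)
    stop(sprintf("insufficient records for summary (%d matching, need >= 2)",
                 length(w)))
  data.frame(n = length(w), mean = mean(w), sd = sd(w),
             min = min(w), max = max(w))
}

midrank <- function(x) rank(x, ties.method = "average")

new_rank_test <- function(...) structure(list(...), class = "rank_test")

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("<rank_test> %s (%s)\n", x$test, x$method))
  if (!is.null(x$ranks)) {
    print(x$ranks, row.names = FALSE)
  }
  cat(sprintf("  statistic = %.4g, p = %.4g (%s at alpha = %.2f)\n",
              x$statistic, x$p_value,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}

#' Wilcoxon signed-rank test, statistics-package style
#'
#' Paired comparison of two measurement methods on the same samples.  Zero
#' differences are dropped; absolute differences are midranked (ties share
#' their mean rank).  The report carries the negative/positive rank counts,
#' mean ranks and rank sums in the layout of the published method-comparison
#' table.  The p-value uses exact enumeration over all sign assignments when
#' at most `exact_limit` non-zero pairs remain, otherwise the normal
#' approximation with tie-corrected variance and no continuity correction.
#'
#' @param x,y paired measurement vectors (same length); the test examines
#'   `y - x`.
#' @param alpha significance level for the `significant` flag.
#' @param exact_limit maximum number of non-zero pairs for exact enumeration.
#' @return A `rank_test` object; `statistic` is the positive rank sum.
#' @export
wilcoxon_signed_rank <- function(x, y, alpha = 0.05, exact_limit = 12L) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  d <- y - x
  nz <- d != 0
  m <- sum(nz)
  if (m == 0L) {
    return(new_rank_test(test = "Wilcoxon signed ranks", method = "degenerate",
                         n = length(x), n_nonzero = 0L, ranks = NULL,
                         statistic = 0, z = 0, p_value = 1,
                         significant = FALSE, alpha = alpha))
  }
  if (m < 5L)
    stop("need at least 5 non-zero-difference pairs")
  dd <- d[nz]
  r <- midrank(abs(dd))
  pos <- dd > 0
  Wpos <- sum(r[pos]); Wneg <- sum(r[!pos])
  ranks <- data.frame(
    ranks = c("negative", "positive"),
    n = c(sum(!pos), sum(pos)),
    mean_rank = c(if (any(!pos)) mean(r[!pos]) else 0,
                  if (any(pos)) mean(r[pos]) else 0),
    sum_ranks = c(Wneg, Wpos))
  mu <- m * (m + 1) / 4
  sigma2 <- sum(r^2) / 4        # tie-corrected: midranks enter directly
  if (m <= exact_limit) {
    # exact null distribution of the positive rank sum over 2^m signs
    W <- 0
    for (ri in r) W <- c(W, W + ri)
    p <- mean(abs(W - mu) >= abs(Wpos - mu) - 1e-9)
    method <- "exact enumeration"
    z <- if (sigma2 > 0) (Wpos - mu) / sqrt(sigma2) else 0
  } else {
    z <- (Wpos - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation, tie-corrected, no continuity correction"
  }
  new_rank_test(test = "Wilcoxon signed ranks", method = method,
                n = length(x), n_nonzero = m, ranks = ranks,
                statistic = Wpos, z = z, p_value = p,
                significant = p < alpha, alpha = alpha)
}

#' Mann-Whitney U test, statistics-package style
#'
#' Two-sample comparison of width records from different treatment groups.
#' Pooled midranks; the report carries per-arm n, mean +/- SD, standard error
#' of the mean, mean rank and rank sum in the layout of the published
#' between-group tables.  Exact enumeration over all group assignments is
#' used when the pooled sample has at most `exact_limit` observations,
#' otherwise the tie-corrected normal approximation without continuity
#' correction.
#'
#' @param x,y measurement vectors for the two arms.
#' @param labels arm labels for the report.
#' @param alpha significance level.
#' @param exact_limit maximum pooled size for exact enumeration.
#' @return A `rank_test` object; `statistic` is U = min(U1, U2).
#' @export
mann_whitney_u <- function(x, y, labels = c("a", "b"), alpha = 0.05,
                           exact_limit = 12L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 3L || n2 < 3L) stop("both arms need at least 3 observations")
  pooled <- c(x, y)
  N <- n1 + n2
  r <- midrank(pooled)
  R1 <- sum(r[seq_len(n1)]); R2 <- sum(r) - R1
  U1 <- R1 - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tiecorr <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tiecorr / (N * (N - 1)))
  arms <- data.frame(
    group = labels,
    n = c(n1, n2),
    mean = c(mean(x), mean(y)),
    sd = c(sd(x), sd(y)),
    sem = c(sd(x) / sqrt(n1), sd(y) / sqrt(n2)),
    mean_rank = c(R1 / n1, R2 / n2),
    sum_ranks = c(R1, R2))
  if (N <= exact_limit) {
    combs <- combn(N, n1)
    Us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U1 - mu) - 1e-9)
    method <- "exact enumeration"
    z <- if (sigma2 > 0) (U1 - mu) / sqrt(sigma2) else 0
  } else {
    z <- if (sigma2 > 0) (U1 - mu) / sqrt(sigma2) else 0
    p <- if (sigma2 > 0) min(1, 2 * pnorm(-abs(z))) else 1
    method <- "normal approximation, tie-corrected, no continuity correction"
  }
  new_rank_test(test = "Mann-Whitney U", method = method,
                n = c(n1, n2), ranks = arms,
                statistic = min(U1, U2), U1 = U1, U2 = U2, z = z,
                p_value = p, significant = p < alpha, alpha = alpha)
}
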