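#' One-tailed two-group test of over-expression
#'
#' Tests whether the values in `x` (cells in a cluster) are greater than
#' those in `y` (cells outside). `welch_t` is the one-tailed Welch
#' unequal-variance t-test, suitable for groups with unequal variances and
#' sizes; `wilcoxon` is the one-tailed rank-sum test, exact when the combined
#' size is at most 20 and there are no ties, otherwise the normal
#' approximation with tie correction.
#'
#' @param x,y numeric value vectors (Welch needs >= 2 per group, Wilcoxon
#'   >= 1).
#' @param test `"welch_t"` or `"wilcoxon"`.
#' @return list with `p.value`, `test`, and `degenerate` (TRUE when both
#'   groups have zero variance: equal means give p = 0.5).
#' @export
two_group_test <- function(x, y, test = c("welch_t", "wilcoxon")) {
  test <- match.arg(test)
  if (test == "welch_t") {
    if (length(x) < 2 || length(y) < 2)
      stop_fmt("welch_t needs >= 2 values per group")
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      mx <- mean(x); my <- mean(y)
      p <- if (mx == my) 0.5 else if (mx > my) 0 else 1
      return(list(p.value = p, test = test, degenerate = TRUE))
    }
    p <- stats::t.test(x, y, alternative = "greater", var.equal = FALSE)$p.value
  } else {
    if (length(x) < 1 || length(y) < 1)
      stop_fmt("wilcoxon needs >= 1 value per group")
    exact <- (length(x) + length(y) <= 20) && !anyDuplicated(c(x, y))
    p <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "greater", exact = exact)$p.value)
  }
  list(p.value = p, test = test, degenerate = FALSE)
}

# Vectorized one-tailed Welch test of rows of `m`: group `in_idx` greater
# than the rest. Zero variance in both groups: p = 0.5 / 0 / 1 by mean order.
welch_greater_rows <- function(m, in_idx) {
  x <- m[, in_idx, drop = FALSE]
  y <- m[, -in_idx, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  t <- (m1 - m2) / sqrt(se2)
  p <- stats::pt(t, df, lower.tail = FALSE)
  deg <- se2 == 0
  p[deg] <- ifelse(m1[deg] == m2[deg], 0.5, ifelse(m1[deg] > m2[deg], 0, 1))
  p
}

#' Per-cluster differential expression
#'
#' For every cluster, each gene is tested for over-expression in the
#' cluster's cells versus all other cells. The Welch t-test is used when both
#' group sizes exceed `min_parametric_n` (default 5); otherwise the Wilcoxon
#' rank-sum test. Benjamini-Hochberg adjustment is applied within each
#' cluster's battery of tests.
#'
#' @param Z numeric genes x cells matrix (the demonstration flow uses
#'   per-sample z-scores) or an `ExpressionMatrix`.
#' @param A a `ClusterAssignment` with k >= 2.
#' @param min_parametric_n both groups must be larger than this for the Welch
#'   test (default 5).
#' @return data frame of class `DEResult` with columns gene_id, cluster,
#'   test, p, q, n_in, n_out; p-values are floored at 1e-300.
#' @export
cluster_differential_expression <- function(Z, A, min_parametric_n = 5) {
  m <- as_values_matrix(Z)
  if (A$k < 2) stop_fmt("differential expression needs >= 2 clusters")
  labels <- A$labels[colnames(m)]
  res <- lapply(sort(unique(labels)), function(cl) {
    in_idx <- which(labels == cl)
    n1 <- length(in_idx); n2 <- ncol(m) - n1
    use_welch <- n1 > min_parametric_n && n2 > min_parametric_n
    if (use_welch) {
      p <- welch_greater_rows(m, in_idx)
    } else {
      p <- vapply(seq_len(nrow(m)), function(i) {
        two_group_test(m[i, in_idx], m[i, -in_idx], "wilcoxon")$p.value
      }, numeric(1))
    }
    p <- pmax(p, 1e-300)
    data.frame(gene_id = rownames(m), cluster = cl,
               test = if (use_welch) "welch_t" else "wilcoxon",
               p = p, q = bh_adjust(p), n_in = n1, n_out = n2,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  class(out) <- c("DEResult", class(out))
  out
}

#' Benjamini-Hochberg step-up adjustment
#' @param p vector of p-values in (0, 1].
#' @return vector of q-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p <= 0 | p > 1)) stop_fmt("p-values must be in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-cluster differentially expressed gene sets
#' @param de a `DEResult`.
#' @param alpha cutoff (default 0.05).
#' @param use column to threshold, `"q"` (default) or `"p"`.
#' @return named list cluster -> character vector of gene IDs.
#' @export
de_gene_sets <- function(de, alpha = 0.05, use = c("q", "p")) {
  use <- match.arg(use)
  lapply(split(de, de$cluster), function(d) d$gene_id[d[[use]] < alpha])
}
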