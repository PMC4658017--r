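#' Per-sample z-score normalization of gene expression
#'
#' Within each sample, every gene is centred and scaled by its own mean and
#' standard deviation over that sample's cells, removing per-sample location
#' and scale differences before clustering. Genes with zero variance in a
#' sample map to 0 there. The transform is idempotent. z-scores are computed
#' on the (floored) abundance scale by default; set `log2_transform` to apply
#' log2(x + 1) first.
#'
#' @param E an `ExpressionMatrix`, or a numeric matrix with a
#'   `"sample_of_cell"` attribute (as returned by this function).
#' @param samples optional named per-cell sample labels when `E` is a plain
#'   matrix.
#' @param log2_transform apply log2(x + 1) before z-scoring (default FALSE).
#' @return numeric genes x cells matrix of z-scores with attribute
#'   `"sample_of_cell"`.
#' @export
zscore_normalize <- function(E, samples = NULL, log2_transform = FALSE) {
  v <- as_values_matrix(E)
  so <- samples_of(E, samples)
  if (log2_transform) v <- log2(v + 1)
  z <- v
  for (s in unique(so)) {
    idx <- which(so == s)
    if (length(idx) < 2) stop_fmt("sample '%s' has fewer than 2 cells", s)
    vs <- v[, idx, drop = FALSE]
    mu <- rowMeans(vs)
    sd <- sqrt(rowSums((vs - mu)^2) / (length(idx) - 1))
    zero <- sd == 0
    sd[zero] <- 1
    zs <- (vs - mu) / sd
    zs[zero, ] <- 0
    z[, idx] <- zs
  }
  attr(z, "sample_of_cell") <- so
  z
}

#' Cell-level normalization by trimmed means
#'
#' Rescales every cell so that its trimmed mean (fraction `trim` removed from
#' each tail) equals the grand mean of all cells' trimmed means; trimming
#' keeps a few extreme transcripts from dominating a cell's size factor.
#'
#' @param E an `ExpressionMatrix`.
#' @param trim fraction trimmed from each tail, in \[0, 0.5) (default 0.05);
#'   `trim = 0` is plain mean scaling.
#' @return the rescaled `ExpressionMatrix`, with the per-cell scale factors
#'   attached as attribute `"scale_factors"`.
#' @export
trimmed_mean_normalize <- function(E, trim = 0.05) {
  if (trim < 0 || trim >= 0.5) stop_fmt("`trim` must be in [0, 0.5)")
  tm <- apply(E$values, 2, mean, trim = trim)
  if (any(tm == 0))
    stop_fmt("cell(s) with zero trimmed mean: %s",
             paste(colnames(E$values)[tm == 0], collapse = ", "))
  target <- mean(tm)
  f <- target / tm
  out <- expression_matrix(sweep(E$values, 2, f, `*`), E$samples)
  attr(out, "scale_factors") <- f
  out
}

#' Quality-control summaries across samples
#'
#' For every sample pair: per-gene MA values (M = log2 mean in the first
#' sample minus log2 mean in the second, A = their average), matched
#' quantile pairs of the two samples' per-gene means (Q-Q), and for every
#' cross-sample cell pair the Pearson correlation of log2(x + 1) expression
#' and the distance 1 - correlation. Diagnostic only; the log2(x + 1)
#' transform stabilizes the variance of abundance-scale data.
#'
#' @param E an `ExpressionMatrix` with >= 2 samples (floored, so means are
#'   positive).
#' @return list of class `qc_summary` with data frames `ma`, `qq` and
#'   `cell_correlation`.
#' @export
qc_summary <- function(E) {
  labs <- sample_labels(E)
  if (length(labs) < 2) stop_fmt("QC summaries need at least 2 samples")
  lg <- log2(E$values + 1)
  means <- vapply(labs, function(s)
    rowMeans(E$values[, E$samples == s, drop = FALSE]),
    numeric(nrow(E$values)))
  means <- matrix(means, nrow = nrow(E$values),
                  dimnames = list(rownames(E$values), labs))
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  ma <- do.call(rbind, lapply(pairs, function(p) {
    l1 <- log2(means[, p[1]]); l2 <- log2(means[, p[2]])
    data.frame(sample_a = p[1], sample_b = p[2], gene_id = rownames(means),
               M = l1 - l2, A = 0.5 * (l1 + l2),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  qq <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(sample_a = p[1], sample_b = p[2],
               quantile_a = sort(means[, p[1]]), quantile_b = sort(means[, p[2]]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  cc <- do.call(rbind, lapply(pairs, function(p) {
    ca <- cells_of_sample(E, p[1]); cb <- cells_of_sample(E, p[2])
    r <- stats::cor(lg[, ca, drop = FALSE], lg[, cb, drop = FALSE])
    data.frame(sample_a = p[1], sample_b = p[2],
               cell_a = rep(ca, times = length(cb)),
               cell_b = rep(cb, each = length(ca)),
               correlation = as.vector(r), distance = 1 - as.vector(r),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(ma = ma, qq = qq, cell_correlation = cc), class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf("qc_summary: %d sample pair(s); %d MA rows; %d cross-sample cell pairs (mean r = %.3f)\n",
              length(unique(paste(x$ma$sample_a, x$ma$sample_b))),
              nrow(x$ma), nrow(x$cell_correlation),
              mean(x$cell_correlation$correlation)))
  invisible(x)
}
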