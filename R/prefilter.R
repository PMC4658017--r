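#' Expression filter: genes detectably expressed in enough cells per sample
#'
#' A gene passes in sample s when at least `n_min` cells of s express it at
#' `theta` or more. Defaults theta = 5 (FPKM), n_min = 2; set `n_min = 1` to
#' retain genes driven by single rare cells.
#'
#' @param E an `ExpressionMatrix`.
#' @param theta abundance threshold (> 0).
#' @param n_min minimal number of expressing cells per sample (>= 1).
#' @return logical genes x samples matrix of pass flags, with the per-sample
#'   expressing-cell counts attached as attribute `"counts"`.
#' @export
expression_filter <- function(E, theta = 5, n_min = 2) {
  if (theta <= 0) stop_fmt("`theta` must be > 0")
  if (n_min < 1) stop_fmt("`n_min` must be >= 1")
  labs <- sample_labels(E)
  q <- vapply(labs, function(s) sum(E$samples == s), integer(1))
  if (n_min > max(q))
    warn_fmt("n_min = %d exceeds the largest sample size (%d); no gene can pass",
             n_min, max(q))
  counts <- vapply(labs, function(s) {
    rowSums(E$values[, E$samples == s, drop = FALSE] >= theta)
  }, numeric(nrow(E$values)))
  counts <- matrix(counts, nrow = nrow(E$values),
                   dimnames = list(rownames(E$values), labs))
  pass <- counts >= n_min
  attr(pass, "counts") <- counts
  pass
}

#' Cell specificity index
#'
#' Per-gene score in \[0, 1\] measuring how restricted a gene's expression is
#' across the cells of one sample. With q cells and min-max rescaled
#' expression x_j, tau = sum_j (1 - x_j) / (q - 1). A gene expressed in
#' exactly one cell attains tau = 1; a constant gene is assigned tau = 0 by
#' convention (the raw formula is 0/0 there, and a constant gene is maximally
#' unselective).
#'
#' @param E an `ExpressionMatrix`.
#' @param sample sample label; the sample must contain >= 2 cells.
#' @return named numeric vector of tau values per gene.
#' @export
specificity_index <- function(E, sample) {
  cells <- cells_of_sample(E, sample)
  q <- length(cells)
  if (q < 2) stop_fmt("sample '%s' has fewer than 2 cells", sample)
  v <- E$values[, cells, drop = FALSE]
  lo <- row_min(v)
  hi <- row_max(v)
  rng <- hi - lo
  const <- rng == 0
  rng[const] <- 1
  x <- (v - lo) / rng
  tau <- rowSums(1 - x) / (q - 1)
  tau[const] <- 0
  stats::setNames(tau, rownames(E$values))
}

#' Gene pre-filtering by expression abundance and cell specificity
#'
#' Keeps genes that pass the expression filter in every sample and have
#' specificity tau >= `tau_min` in every sample (section 1). The report labels
#' the other genes: section 2 passed the expression filter everywhere but
#' failed specificity, section 3 passed the expression filter in no sample,
#' section 4 passed it in some but not all samples. The four sections
#' partition the gene set.
#'
#' @param E an `ExpressionMatrix`.
#' @param theta,n_min expression-filter parameters (defaults 5 and 2).
#' @param tau_min specificity cutoff in \[0, 1\] (default 0.7).
#' @return list with `matrix` (the `ExpressionMatrix` restricted to kept
#'   genes) and `report` (class `PrefilterReport`: data frame with gene_id,
#'   section, kept plus attributes `pass`, `counts`, `tau`).
#' @export
prefilter <- function(E, theta = 5, n_min = 2, tau_min = 0.7) {
  if (tau_min < 0 || tau_min > 1) stop_fmt("`tau_min` must be in [0, 1]")
  labs <- sample_labels(E)
  pass <- expression_filter(E, theta, n_min)
  tau <- vapply(labs, function(s) specificity_index(E, s),
                numeric(nrow(E$values)))
  tau <- matrix(tau, nrow = nrow(E$values),
                dimnames = list(rownames(E$values), labs))
  expr_all <- rowSums(pass) == length(labs)
  expr_none <- rowSums(pass) == 0
  tau_all <- rowSums(tau >= tau_min) == length(labs)
  section <- ifelse(expr_all & tau_all, 1L,
             ifelse(expr_all, 2L,
             ifelse(expr_none, 3L, 4L)))
  kept <- section == 1L
  report <- data.frame(gene_id = rownames(E$values), section = section,
                       kept = kept, stringsAsFactors = FALSE, row.names = NULL)
  attr(report, "pass") <- pass
  attr(report, "counts") <- attr(pass, "counts")
  attr(report, "tau") <- tau
  class(report) <- c("PrefilterReport", class(report))
  kept_E <- expression_matrix(E$values[kept, , drop = FALSE], E$samples)
  list(matrix = kept_E, report = report)
}

#' @export
print.PrefilterReport <- function(x, ...) {
  tab <- table(factor(x$section, levels = 1:4))
  cat(sprintf(paste0("PrefilterReport: %d genes; kept %d\n",
                     "  section 1 (both filters passed):      %d\n",
                     "  section 2 (failed specificity):       %d\n",
                     "  section 3 (failed expression filter): %d\n",
                     "  section 4 (expression filter mixed):  %d\n"),
              nrow(x), sum(x$kept), tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}
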