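#' Cell-type enrichment of per-cluster gene lists
#'
#' For each (cluster, cell type) pair, a one-tailed (over-representation)
#' Fisher's exact test on the 2x2 table of membership in the cluster's gene
#' list versus the cell type's gene set, over a fixed gene universe
#' (typically the genes surviving pre-filtering, the only genes eligible to
#' be differentially expressed). Benjamini-Hochberg adjustment across cell
#' types within each cluster; rows sorted by increasing p within cluster.
#'
#' @param de_genes named list cluster -> character vector of genes (e.g. from
#'   [de_gene_sets()]); each list must be non-empty and inside the universe.
#' @param sets a `GeneSetCollection` or named list of gene sets.
#' @param universe character vector of gene IDs containing every tested gene.
#' @return data frame of class `EnrichmentResult` with the table counts, odds
#'   ratio, p and q per (cluster, cell_type).
#' @export
celltype_enrichment <- function(de_genes, sets, universe) {
  if (inherits(sets, "GeneSetCollection")) sets <- sets$sets
  universe <- unique(universe)
  out <- lapply(names(de_genes), function(cl) {
    lst <- unique(de_genes[[cl]])
    if (length(lst) == 0) stop_fmt("empty gene list for cluster '%s'", cl)
    if (!all(lst %in% universe))
      stop_fmt("cluster '%s' gene list outside the universe", cl)
    rows <- lapply(names(sets), function(ct) {
      st <- intersect(unique(sets[[ct]]), universe)
      a <- length(intersect(lst, st))
      b <- length(lst) - a
      cc <- length(st) - a
      d <- length(universe) - a - b - cc
      ft <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2),
                               alternative = "greater")
      data.frame(cluster = cl, cell_type = ct, overlap = a,
                 list_size = length(lst), set_size = length(st),
                 universe_size = length(universe),
                 odds_ratio = unname(ft$estimate), p = ft$p.value,
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    d <- do.call(rbind, rows)
    d$q <- bh_adjust(d$p)
    d[order(d$p), ]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", class(out))
  out
}

#' Aggregate per-marker cell rankings into a consensus ranking
#'
#' Each marker ranks all N cells by descending expression (average ranks on
#' ties, normalized to r = rank / N). Under `"rra"` (robust rank
#' aggregation), a cell's score is rho = min over k of P(X >= k) with
#' X ~ Binomial(m, r_(k)) evaluated at the cell's k-th smallest normalized
#' rank -- small rho means the cell sits improbably high under several
#' markers. `"borda"` uses the mean normalized rank. Cells are ordered by
#' ascending score (ties broken by cell ID for a reproducible ordering).
#'
#' @param E an `ExpressionMatrix` (or genes x cells matrix).
#' @param markers character vector of marker gene IDs; markers absent from
#'   the matrix are dropped with a warning, all absent is an error.
#' @param method `"rra"` (default) or `"borda"`.
#' @return list of class `marker_ranking` with `scores` (named, per cell),
#'   `ranking` (cell IDs, best first), `rank` (named average ranks of the
#'   scores), `markers_used`, `method`.
#' @export
aggregate_marker_ranks <- function(E, markers, method = c("rra", "borda")) {
  method <- match.arg(method)
  v <- as_values_matrix(E)
  present <- intersect(markers, rownames(v))
  if (length(present) == 0) stop_fmt("no marker present in the matrix")
  if (length(present) < length(markers))
    warn_fmt("markers absent from the matrix dropped: %s",
             paste(setdiff(markers, present), collapse = ", "))
  n <- ncol(v)
  m <- length(present)
  # rows: markers; cols: cells; normalized descending-expression ranks
  R <- t(apply(v[present, , drop = FALSE], 1,
               function(x) rank(-x, ties.method = "average") / n))
  R <- matrix(R, nrow = m, dimnames = list(present, colnames(v)))
  scores <- if (method == "rra") {
    apply(R, 2, function(r) {
      rs <- sort(r)
      min(stats::pbinom(seq_len(m) - 1, m, rs, lower.tail = FALSE))
    })
  } else {
    colMeans(R)
  }
  ranking <- colnames(v)[order(scores, colnames(v))]
  structure(list(scores = scores, ranking = ranking,
                 rank = rank(scores, ties.method = "average"),
                 markers_used = present, method = method),
            class = "marker_ranking")
}

#' @export
print.marker_ranking <- function(x, ...) {
  cat(sprintf("marker_ranking (%s): %d cells, %d markers; top cell %s\n",
              x$method, length(x$scores), length(x$markers_used), x$ranking[1]))
  invisible(x)
}

#' AUC of a cell ranking against a cell-type assignment
#'
#' Positives are the assigned cells, negatives the rest; the AUC is the
#' probability that a random positive outranks a random negative, computed
#' from the rank-sum identity AUC = U / (n+ * n-); tied ranks contribute 1/2.
#'
#' @param ranking a `marker_ranking`, or a named numeric vector of ranks
#'   (1 = best, average ranks on ties) over all cells.
#' @param assigned character vector of cell IDs labelled as the cell type
#'   (non-empty, not all cells).
#' @return the AUC, in \[0, 1\].
#' @export
marker_validation_auc <- function(ranking, assigned) {
  r <- if (inherits(ranking, "marker_ranking")) ranking$rank else ranking
  if (is.null(names(r))) stop_fmt("ranking must be named by cell ID")
  pos <- names(r) %in% assigned
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop_fmt("degenerate split: need both assigned and unassigned cells")
  # score = -rank (higher better); re-rank to keep tie handling exact
  s <- rank(-r, ties.method = "average")
  (sum(s[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
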