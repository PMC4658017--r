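#' Candidate transcription factors and regulatory targets for one cluster
#'
#' T = catalog genes that are either differentially expressed in the cluster
#' (p < `p_tf`, default 0.05) or commonly expressed there (mc = 1, i.e.
#' expressed in at least 80 percent of cluster cells by default);
#' G = genes differentially expressed at p < `p_target` (default 0.01).
#' Both restricted to genes present in the expression matrix.
#'
#' @param de a `DEResult`.
#' @param metrics a `SignatureMetrics` data frame for the cluster (provides
#'   mc).
#' @param cluster cluster label.
#' @param tf_catalog character vector of verified TF / transcription
#'   cofactor gene IDs.
#' @param p_tf,p_target selection thresholds.
#' @return list with `tfs` and `targets` (character vectors).
#' @export
select_candidates <- function(de, metrics, cluster, tf_catalog,
                              p_tf = 0.05, p_target = 0.01) {
  if (length(tf_catalog) == 0) stop_fmt("empty TF catalog")
  dcl <- de[de$cluster == cluster, ]
  p <- stats::setNames(dcl$p, dcl$gene_id)
  mc <- stats::setNames(metrics$mc, metrics$gene_id)
  genes <- metrics$gene_id
  tfs <- genes[genes %in% tf_catalog &
                 (p[genes] < p_tf | mc[genes] == 1)]
  targets <- genes[p[genes] < p_target]
  if (length(tfs) < 2)
    warn_fmt("fewer than 2 candidate TFs; first-order conditioning degenerates")
  list(tfs = tfs, targets = targets)
}

# p-value (two-sided t) for the coefficient of x1 in the least-squares fit
# y ~ 1 + x1 [+ x2]; closed-form normal equations.
coef_p_value <- function(y, x1, x2 = NULL) {
  X <- if (is.null(x2)) cbind(1, x1) else cbind(1, x1, x2)
  n <- length(y)
  df <- n - ncol(X)
  if (df <= 0) stop_fmt("too few observations for the regression")
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * solve(XtX)[2, 2])
  if (se == 0) return(list(p = if (b[2] == 0) 1 else 0, coef = b[2]))
  t <- b[2] / se
  list(p = 2 * stats::pt(-abs(t), df), coef = unname(b[2]))
}

#' First-order conditional-dependence network inference
#'
#' For every candidate pair (i in T, j in G, i != j) and every conditioning
#' TF k in T \ \{i, j\}, the linear model
#' X_j = m + a_ij|k X_i + a_kj|i X_k + noise is fitted by least squares over
#' the cluster's cells, and p_ij|k is the t-test p-value for a_ij|k = 0.
#' The edge significance S_ij = max_k p_ij|k is the worst case over all
#' single-TF conditionings; the edge is retained when S_ij < `cutoff`
#' (default 0.05). With fewer than 3 TFs (or when every conditioning TF is
#' collinear with i) the marginal regression p is used. Feedback from
#' targets to TFs and TF self-loops are excluded by construction.
#'
#' @param X genes x cells matrix restricted to the cluster's cells (>= 5
#'   cells); rows must cover all TFs and targets.
#' @param tfs,targets candidate sets, e.g. from [select_candidates()].
#' @param cutoff retention threshold on S (default 0.05).
#' @return object of class `RegulatoryNetwork`: list with `edges` (data
#'   frame tf, target, S, coef_sign -- sign of the marginal regression
#'   coefficient), `tfs`, `targets`, `cutoff`.
#' @export
infer_first_order_edges <- function(X, tfs, targets, cutoff = 0.05) {
  X <- as_values_matrix(X)
  if (ncol(X) < 5) stop_fmt("need >= 5 cells for edge inference")
  miss <- setdiff(c(tfs, targets), rownames(X))
  if (length(miss) > 0)
    stop_fmt("genes absent from the matrix: %s", paste(miss, collapse = ", "))
  edges <- list()
  for (i in tfs) {
    xi <- X[i, ]
    if (stats::sd(xi) == 0) next
    for (j in setdiff(targets, i)) {
      yj <- X[j, ]
      ks <- setdiff(tfs, c(i, j))
      ps <- numeric(0)
      for (k in ks) {
        xk <- X[k, ]
        if (stats::sd(xk) == 0 ||
            abs(suppressWarnings(stats::cor(xi, xk))) > 1 - 1e-10) {
          warn_fmt("conditioning TF '%s' collinear with '%s'; skipped", k, i)
          next
        }
        ps <- c(ps, coef_p_value(yj, xi, xk)$p)
      }
      marg <- coef_p_value(yj, xi)
      S <- if (length(ps) == 0) marg$p else max(ps)
      if (S < cutoff)
        edges[[length(edges) + 1]] <-
          data.frame(tf = i, target = j, S = S, coef_sign = sign(marg$coef),
                     stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges) == 0) {
    data.frame(tf = character(0), target = character(0), S = numeric(0),
               coef_sign = numeric(0), stringsAsFactors = FALSE)
  } else do.call(rbind, edges)
  structure(list(edges = edges, tfs = tfs, targets = targets, cutoff = cutoff),
            class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat(sprintf("RegulatoryNetwork: %d edge(s) (S < %g) from %d TFs to %d targets\n",
              nrow(x$edges), x$cutoff, length(x$tfs), length(x$targets)))
  invisible(x)
}

as_undirected_graph <- function(net) {
  if (inherits(net, "RegulatoryNetwork")) {
    if (nrow(net$edges) == 0) stop_fmt("network has no edges")
    g <- igraph::graph_from_data_frame(net$edges[, c("tf", "target")],
                                       directed = FALSE)
    igraph::simplify(g)
  } else if (inherits(net, "igraph")) {
    igraph::as_undirected(net, mode = "collapse")
  } else stop_fmt("expected a RegulatoryNetwork or igraph object")
}

#' Main connected component of a regulatory network
#'
#' Largest connected component under the undirected view of the edge set
#' (size ties resolved in favour of the component containing the
#' lexicographically smallest node ID). Node-importance metrics are computed
#' on this component.
#'
#' @param net a `RegulatoryNetwork` with >= 1 edge (or an igraph graph).
#' @return undirected igraph graph of the main component.
#' @export
main_component <- function(net) {
  g <- as_undirected_graph(net)
  comp <- igraph::components(g)
  mx <- max(comp$csize)
  cand <- which(comp$csize == mx)
  if (length(cand) > 1) {
    firsts <- vapply(cand, function(ci)
      min(igraph::V(g)$name[comp$membership == ci]), character(1))
    cand <- cand[order(firsts)][1]
  }
  igraph::induced_subgraph(g, which(comp$membership == cand))
}

#' Six node-importance metrics on a connected graph
#'
#' On the undirected view of the network's main component with N nodes:
#' * DC: degree -- the number of adjacent nodes.
#' * CC: closeness, 1 / (sum of geodesic distances to all other nodes).
#' * BC: betweenness -- the number of shortest paths through the node,
#'   counted over ordered pairs (both directions), unnormalized; only the
#'   induced ranks are consumed downstream, for which any consistent
#'   convention is equivalent.
#' * DFC: K_i / (N - 1), where K_i is the number of connected components
#'   after deleting node i.
#' * DCC: 1 - (number of ordered pairs j != k still mutually reachable after
#'   deleting i) / ((N - 1)(N - 2)).
#' * DDC: 1 - (sum over ordered pairs j != k of 1 / d(j, k) in the residual
#'   graph, with 1 / infinity = 0) / ((N - 1)(N - 2)).
#'
#' @param g a connected undirected igraph graph with >= 3 nodes (e.g. from
#'   [main_component()]).
#' @return data frame of class `NodeImportanceTable` with node, DC, CC, BC,
#'   DFC, DCC, DDC.
#' @export
node_importance <- function(g) {
  g <- as_undirected_graph(g)
  if (!igraph::is_connected(g))
    stop_fmt("graph is disconnected; run main_component() first")
  N <- igraph::vcount(g)
  if (N < 3) stop_fmt("need >= 3 nodes")
  nodes <- igraph::V(g)$name
  dc <- igraph::degree(g)
  cc <- 1 / rowSums(igraph::distances(g))
  bc <- 2 * igraph::betweenness(g, directed = FALSE)
  resid <- vapply(seq_len(N), function(i) {
    h <- igraph::delete_vertices(g, i)
    comp <- igraph::components(h)
    d <- igraph::distances(h)
    off <- row(d) != col(d)
    reach <- sum(is.finite(d[off]))
    invd <- sum(1 / d[off & is.finite(d)])
    c(K = comp$no, reach = reach, invd = invd)
  }, numeric(3))
  denom <- (N - 1) * (N - 2)
  out <- data.frame(node = nodes,
                    DC = unname(dc), CC = unname(cc), BC = unname(bc),
                    DFC = resid["K", ] / (N - 1),
                    DCC = 1 - resid["reach", ] / denom,
                    DDC = 1 - resid["invd", ] / denom,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("NodeImportanceTable", class(out))
  out
}

#' Rank transcription factors by the six importance metrics
#'
#' Per metric, TFs are ranked in descending value order with competition
#' ("min") ranks -- tied TFs share the smallest rank of their tie block. The
#' final node importance is the arithmetic mean of the six ranks, and the
#' final ordering is ascending in average rank, tied TFs sharing a position.
#'
#' @param table a `NodeImportanceTable`.
#' @param tf_nodes TFs to rank (others in the component are targets only).
#' @return data frame with the six per-metric ranks, `average_rank`, and the
#'   shared final `position`, sorted by position then TF ID.
#' @export
rank_transcription_factors <- function(table, tf_nodes) {
  d <- table[table$node %in% tf_nodes, ]
  if (nrow(d) == 0) stop_fmt("no TF present in the importance table")
  metrics <- c("DC", "CC", "BC", "DFC", "DCC", "DDC")
  ranks <- vapply(metrics, function(mt) rank(-d[[mt]], ties.method = "min"),
                  numeric(nrow(d)))
  ranks <- matrix(ranks, nrow = nrow(d),
                  dimnames = list(NULL, paste0("rank_", metrics)))
  avg <- rowMeans(ranks)
  out <- data.frame(tf = d$node, ranks, average_rank = avg,
                    position = rank(avg, ties.method = "min"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$position, out$tf), ]
  rownames(out) <- NULL
  out
}

#' Sensitivity and relative power of the six importance metrics
#'
#' Sensitivity of a metric is the mean tie-block width of the ranking it
#' induces (1 when all values are distinct, the number of TFs when all are
#' tied); low sensitivity means coarse resolution. Relative power is the
#' Spearman rank correlation between the metric's ranking and the final
#' average ranking, normalized so the six powers average to 1; it measures
#' each metric's contribution to the consensus.
#'
#' @param table a `NodeImportanceTable`.
#' @param tf_nodes TFs over which the metrics are compared.
#' @return data frame with metric, sensitivity, relative_power.
#' @export
metric_diagnostics <- function(table, tf_nodes) {
  d <- table[table$node %in% tf_nodes, ]
  metrics <- c("DC", "CC", "BC", "DFC", "DCC", "DDC")
  ranking <- rank_transcription_factors(table, tf_nodes)
  avg <- ranking$average_rank[match(d$node, ranking$tf)]
  sens <- vapply(metrics, function(mt) mean(table(d[[mt]])), numeric(1))
  power <- vapply(metrics, function(mt) {
    r <- suppressWarnings(
      stats::cor(rank(-d[[mt]]), rank(avg), method = "spearman"))
    if (is.na(r)) 0 else r   # a fully tied metric carries no ordering
  }, numeric(1))
  data.frame(metric = metrics, sensitivity = unname(sens),
             relative_power = unname(power / mean(power)),
             stringsAsFactors = FALSE, row.names = NULL)
}
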