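#' Cell-cell distance matrix
#'
#' Default metric is centered Pearson correlation distance d = 1 - r between
#' the cells' gene vectors (range \[0, 2\]); the trend of expression across
#' genes matters more than absolute distance for cell-type structure.
#' Euclidean distance is available as an alternative.
#'
#' @param Z numeric genes x cells matrix (typically per-sample z-scores).
#' @param metric `"centered_pearson"` or `"euclidean"`.
#' @return symmetric cells x cells distance matrix with zero diagonal and a
#'   `"metric"` attribute.
#' @export
cell_distance_matrix <- function(Z, metric = c("centered_pearson", "euclidean")) {
  metric <- match.arg(metric)
  Z <- as_values_matrix(Z)
  if (ncol(Z) < 2 || nrow(Z) < 2) stop_fmt("need >= 2 cells and >= 2 genes")
  if (metric == "centered_pearson") {
    sds <- apply(Z, 2, stats::sd)
    if (any(sds == 0))
      stop_fmt("constant cell vector(s), correlation undefined: %s",
               paste(colnames(Z)[sds == 0], collapse = ", "))
    D <- 1 - stats::cor(Z)
  } else {
    D <- as.matrix(stats::dist(t(Z)))
  }
  diag(D) <- 0
  attr(D, "metric") <- metric
  D
}

#' Hierarchical clustering of cells with automatic threshold selection
#'
#' Agglomerative clustering (average linkage by default) cut either at a
#' fixed `threshold` height, into a fixed number of clusters `k`, or -- when
#' neither is given -- at the minimum merge height whose clustering contains
#' no more than `gamma` singleton clusters (default gamma = 0). Clusters are
#' labelled C1, C2, ... in decreasing size order (ties by smallest cell ID);
#' cells are processed in lexicographic ID order so the result does not
#' depend on input order.
#'
#' @param D symmetric distance matrix from [cell_distance_matrix()].
#' @param linkage `"average"` or `"ward"` (Ward linkage with a correlation
#'   distance triggers a warning but is tolerated).
#' @param threshold optional cut height.
#' @param k optional number of clusters.
#' @param gamma maximum number of singleton clusters for the automatic
#'   threshold search (default 0).
#' @return object of class `ClusterAssignment`: list with `labels` (named
#'   cell -> cluster label), `k`, `sizes`, `heights` (merge heights),
#'   `hclust`, and `cut` (how the tree was cut).
#' @export
hierarchical_clusters <- function(D, linkage = c("average", "ward"),
                                  threshold = NULL, k = NULL, gamma = 0) {
  linkage <- match.arg(linkage)
  if (!is.null(threshold) && !is.null(k))
    stop_fmt("give at most one of `threshold` and `k`")
  if (linkage == "ward" && identical(attr(D, "metric"), "centered_pearson"))
    warn_fmt("Ward linkage with a correlation distance mixes metrics; proceeding")
  ord <- order(colnames(D))
  D <- D[ord, ord]
  hc <- stats::hclust(stats::as.dist(D),
                      method = if (linkage == "ward") "ward.D2" else "average")
  if (!is.null(threshold)) {
    raw <- stats::cutree(hc, h = threshold)
    cut <- list(type = "threshold", value = threshold)
  } else if (!is.null(k)) {
    raw <- stats::cutree(hc, k = k)
    cut <- list(type = "k", value = k)
  } else {
    heights <- sort(unique(hc$height))
    raw <- NULL
    for (h in heights) {
      cand <- stats::cutree(hc, h = h)
      if (sum(table(cand) == 1) <= gamma) {
        raw <- cand
        cut <- list(type = "gamma", value = gamma, height = h)
        break
      }
    }
    if (is.null(raw)) { # unreachable: the single-cluster cut has 0 singletons
      raw <- stats::cutree(hc, k = 1)
      cut <- list(type = "gamma", value = gamma, height = max(hc$height))
    }
  }
  labels <- relabel_by_size(raw)
  structure(list(labels = labels, k = length(unique(labels)),
                 sizes = table(labels), heights = hc$height, hclust = hc,
                 cut = cut),
            class = "ClusterAssignment")
}

# C1..Ck in decreasing size order; size ties broken by the lexicographically
# smallest member cell ID.
relabel_by_size <- function(raw) {
  ids <- names(raw)
  sizes <- table(raw)
  first <- vapply(names(sizes), function(cl) min(ids[raw == cl]), character(1))
  ord <- names(sizes)[order(-as.vector(sizes), first)]
  new <- stats::setNames(paste0("C", seq_along(ord)), ord)
  stats::setNames(unname(new[as.character(raw)]), ids)
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d cells in %d cluster(s) [%s]\n",
              length(x$labels), x$k,
              paste(sprintf("%s:%d", names(x$sizes), x$sizes), collapse = ", ")))
  invisible(x)
}

#' Cells belonging to one cluster
#' @param A a `ClusterAssignment`.
#' @param cluster a cluster label.
#' @return character vector of cell IDs.
#' @export
cluster_cells <- function(A, cluster) {
  if (!cluster %in% A$labels) stop_fmt("unknown cluster '%s'", cluster)
  names(A$labels)[A$labels == cluster]
}

#' Cluster separation statistic
#'
#' Mean within-cluster cell-cell Pearson correlation minus mean
#' between-cluster correlation; large positive values indicate well-separated
#' clusters.
#'
#' @param Z numeric genes x cells matrix.
#' @param labels named per-cell cluster labels with >= 2 clusters.
#' @return the statistic (single number).
#' @export
cluster_separation_statistic <- function(Z, labels) {
  Z <- as_values_matrix(Z)
  labels <- labels[colnames(Z)]
  if (length(unique(labels)) < 2)
    stop_fmt("statistic needs >= 2 clusters (no between-cluster term otherwise)")
  r <- stats::cor(Z)
  same <- outer(labels, labels, `==`)
  ut <- upper.tri(r)
  mean(r[ut & same]) - mean(r[ut & !same])
}

#' Permutation significance of a clustering scheme
#'
#' Observed statistic: [cluster_separation_statistic()]. Null model: each
#' gene's values are independently permuted across cells (preserving gene
#' marginals, destroying gene-gene and cell-cell structure), the permuted
#' matrix is re-clustered with identical settings, and the statistic is
#' recomputed. Reports the upper-tail normal-approximation p-value from the B
#' null values (which can be far below 1/B) and the empirical p-value
#' (#\{null >= observed\} + 1) / (B + 1).
#'
#' @param Z numeric genes x cells matrix (typically per-sample z-scores).
#' @param A the observed `ClusterAssignment` (k >= 2).
#' @param B number of permutations (>= 20, default 100).
#' @param seed integer seed for the permutations.
#' @param linkage,metric clustering settings used for re-clustering.
#' @param cut how to cut the permuted tree: `list(type = "threshold"|"k"|"gamma",
#'   value = ...)`; defaults to the cut recorded in `A`. A permuted clustering
#'   with a single cluster contributes a null statistic of 0 (no separation).
#' @return list with `statistic`, `null_mean`, `null_sd`, `p_normal`,
#'   `p_empirical`, `B`, and the vector of `null` statistics.
#' @export
permutation_significance <- function(Z, A, B = 100, seed = NULL,
                                     linkage = "average",
                                     metric = "centered_pearson", cut = NULL) {
  if (B < 20) stop_fmt("`B` must be >= 20")
  if (A$k < 2) stop_fmt("clustering has a single cluster")
  Z <- as_values_matrix(Z)
  cut <- cut %||% A$cut
  obs <- cluster_separation_statistic(Z, A$labels)
  recluster_stat <- function(M) {
    D <- cell_distance_matrix(M, metric)
    Ab <- switch(cut$type,
      threshold = hierarchical_clusters(D, linkage, threshold = cut$value),
      k = hierarchical_clusters(D, linkage, k = cut$value),
      gamma = hierarchical_clusters(D, linkage, gamma = cut$value))
    if (Ab$k < 2) return(0)
    t <- cluster_separation_statistic(M, Ab$labels)
    # all-singleton (or one-block) permuted clusterings have no within- or
    # between-cluster pairs: no separation by convention
    if (is.nan(t)) 0 else t
  }
  null <- with_seed_opt(seed, {
    vapply(seq_len(B), function(b) {
      P <- t(apply(Z, 1, sample))
      dimnames(P) <- dimnames(Z)
      recluster_stat(P)
    }, numeric(1))
  })
  mu <- mean(null); sd <- stats::sd(null)
  p_norm <- if (sd == 0) as.numeric(obs <= mu) else
    stats::pnorm(obs, mean = mu, sd = sd, lower.tail = FALSE)
  list(statistic = obs, null_mean = mu, null_sd = sd,
       p_normal = p_norm,
       p_empirical = (sum(null >= obs) + 1) / (B + 1),
       B = B, null = null)
}
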