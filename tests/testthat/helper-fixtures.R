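# Fixture builders and independent oracles shared across the test files.
# Oracles are deliberately naive (enumeration, pair counting, BFS on an
# adjacency matrix) and never call the code paths they check.

tiny_expression_matrix <- function() {
  v <- matrix(c(5, 0, 1, 2,
                0, 8, 0, 3,
                7, 7, 7, 7), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("c1", "c2", "c3", "c4")))
  expression_matrix(v, c(c1 = "S1", c2 = "S1", c3 = "S2", c4 = "S2"))
}

random_expression_matrix <- function(n_genes = 20, n_cells = 10,
                                     n_samples = 2, seed = 1) {
  withr::with_seed(seed, {
    v <- matrix(stats::rlnorm(n_genes * n_cells, 1, 1), nrow = n_genes,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("c%02d", seq_len(n_cells))))
    so <- stats::setNames(paste0("S", rep_len(seq_len(n_samples), n_cells)),
                          colnames(v))
    expression_matrix(v, so)
  })
}

# Adjusted Rand index between two labelings (closed form on the
# contingency table).
ari <- function(x, y) {
  t <- table(x, y)
  a <- sum(choose(t, 2))
  b <- sum(choose(rowSums(t), 2))
  cc <- sum(choose(colSums(t), 2))
  n <- choose(sum(t), 2)
  (a - b * cc / n) / ((b + cc) / 2 - b * cc / n)
}

# Exact one-tailed rank-sum p-value P(W >= w_obs) by enumerating every
# assignment of the combined sample to the first group.
wilcox_enum_p <- function(x, y) {
  z <- c(x, y)
  stopifnot(!anyDuplicated(z))
  r <- rank(z)
  w_obs <- sum(r[seq_along(x)])
  combos <- utils::combn(length(z), length(x))
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(ws >= w_obs)
}

# Hypergeometric upper-tail P(X >= a) via log-binomials.
hyper_tail_p <- function(a, list_size, set_size, universe_size) {
  kmax <- min(list_size, set_size)
  if (a > kmax) return(0)
  lp <- vapply(a:kmax, function(k)
    lchoose(set_size, k) + lchoose(universe_size - set_size, list_size - k) -
      lchoose(universe_size, list_size), numeric(1))
  sum(exp(lp))
}

# Step-up BH by definition: q_i = min over p_j >= p_i of min(1, m p_j / rank_j).
bh_enum <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i])
    min(1, min(m * p[js] / r[js]))
  }, numeric(1))
}

# AUC by O(n^2) concordant-pair counting; `r` are ranks (1 = best), ties 1/2.
auc_pairs <- function(r, pos) {
  rp <- r[pos]; rn <- r[!pos]
  s <- 0
  for (a in rp) for (b in rn) s <- s + (a < b) + 0.5 * (a == b)
  s / (length(rp) * length(rn))
}

# ---- graph oracles on a 0/1 adjacency matrix ----

# BFS from s: geodesic distances and shortest-path counts.
bfs_paths <- function(adj, s) {
  n <- nrow(adj)
  dist <- rep(Inf, n); nsp <- rep(0, n)
  dist[s] <- 0; nsp[s] <- 1
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in which(adj[u, ] == 1)) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          nxt <- c(nxt, v)
          nsp[v] <- nsp[v] + nsp[u]
        } else if (dist[v] == dist[u] + 1) {
          nsp[v] <- nsp[v] + nsp[u]
        }
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, nsp = nsp)
}

n_components <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(0)
  seen <- rep(FALSE, n); comp <- 0
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1
    stack <- s
    while (length(stack) > 0) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[u]) next
      seen[u] <- TRUE
      stack <- c(stack, which(adj[u, ] == 1 & !seen))
    }
  }
  comp
}

# All six importance metrics by brute force.
oracle_importance <- function(adj) {
  n <- nrow(adj)
  bfs <- lapply(seq_len(n), function(s) bfs_paths(adj, s))
  dist <- t(vapply(bfs, `[[`, numeric(n), "dist"))
  nsp <- t(vapply(bfs, `[[`, numeric(n), "nsp"))
  dc <- rowSums(adj)
  cc <- 1 / vapply(seq_len(n), function(i) sum(dist[i, -i]), numeric(1))
  bc <- vapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j == k || j == i || k == i) next
      if (dist[j, i] + dist[i, k] == dist[j, k])
        s <- s + (nsp[j, ][i] * nsp[i, ][k]) / nsp[j, ][k]
    }
    s
  }, numeric(1))
  dfc <- dcc <- ddc <- numeric(n)
  for (i in seq_len(n)) {
    sub <- adj[-i, -i, drop = FALSE]
    dfc[i] <- n_components(sub) / (n - 1)
    m <- nrow(sub)
    dsub <- t(vapply(seq_len(m), function(s) bfs_paths(sub, s)$dist, numeric(m)))
    off <- row(dsub) != col(dsub)
    dcc[i] <- 1 - sum(is.finite(dsub[off])) / ((n - 1) * (n - 2))
    ddc[i] <- 1 - sum(1 / dsub[off & is.finite(dsub)]) / ((n - 1) * (n - 2))
  }
  data.frame(DC = dc, CC = cc, BC = bc, DFC = dfc, DCC = dcc, DDC = ddc)
}

# Random connected labelled graph as an adjacency matrix.
random_connected_adj <- function(n, p = 0.35, seed = NULL) {
  gen <- function() {
    adj <- matrix(0, n, n)
    for (a in seq_len(n - 1)) for (b in (a + 1):n)
      if (stats::runif(1) < p) adj[a, b] <- adj[b, a] <- 1
    adj
  }
  f <- function() {
    repeat {
      adj <- gen()
      if (n_components(adj) == 1 && sum(adj) > 0) return(adj)
    }
  }
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}

adj_to_graph <- function(adj) {
  dimnames(adj) <- list(sprintf("n%02d", seq_len(nrow(adj))),
                        sprintf("n%02d", seq_len(nrow(adj))))
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# Standard planted-cluster fixture used by several files.
planted_fixture <- function(seed = 7, program = FALSE) {
  cfg <- simulation_config(seed = seed,
                           program_tfs_per_cluster = if (program) 2 else 0)
  sim <- simulate_cells(cfg)
  pf <- prefilter(sim$matrix)
  Z <- zscore_normalize(pf$matrix)
  # demonstration defaults: distance threshold 0.5 on the 1 - r scale
  A <- hierarchical_clusters(cell_distance_matrix(Z), threshold = 0.5)
  list(sim = sim, E = pf$matrix, Z = Z, A = A)
}

# Write a simulated fixture's input files the way the pipeline reads them.
write_fixture_inputs <- function(dir, sim) {
  write_expression_matrix(sim$matrix, file.path(dir, "matrix.tsv"),
                          file.path(dir, "metadata.tsv"))
  mk <- do.call(rbind, lapply(names(sim$markers$markers), function(ct)
    data.frame(cell_type = ct, gene = sim$markers$markers[[ct]])))
  write.table(mk, file.path(dir, "markers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$association, file.path(dir, "association.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(c("gene", sim$tf_catalog), file.path(dir, "tf_catalog.tsv"))
  list(matrix = file.path(dir, "matrix.tsv"),
       metadata = file.path(dir, "metadata.tsv"),
       markers = file.path(dir, "markers.tsv"),
       gene_sets = file.path(dir, "association.tsv"),
       gene_sets_format = "association_table",
       tf_catalog = file.path(dir, "tf_catalog.tsv"))
}

# Inferred cluster label containing the majority of a true cluster's cells.
matched_cluster <- function(A, labels, true_cluster) {
  names(which.max(table(A$labels[names(labels)[labels == true_cluster]])))
}
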