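#' Configuration for the synthetic single-cell fixture generator
#'
#' Defines a log-normal abundance model of clustered cell populations:
#' per-cluster signature genes elevated by a log2-fold effect in their own
#' cluster only, housekeeping genes highly and uniformly expressed
#' everywhere (low cell specificity), low-expression genes that fail the
#' expression filter, multiplicative per-batch scale factors, and optional
#' linear TF -> target regulatory programs planted within each cluster.
#'
#' @param n_clusters number of cell clusters (>= 2).
#' @param cells_per_cluster integer vector (recycled) of cells per cluster.
#' @param n_signature_genes signature genes per cluster.
#' @param n_housekeeping housekeeping genes.
#' @param n_noise_genes low-expression genes.
#' @param elevation signature log2-fold elevation inside the own cluster.
#' @param baseline_log2,housekeeping_log2,noise_log2 log2 mean abundances of
#'   background, housekeeping and low-expression genes.
#' @param noise_sd SD of the log2-scale expression noise.
#' @param batch_scale multiplicative per-batch scale factors (one batch per
#'   entry); cells of every cluster are spread across all batches.
#' @param n_markers markers per cluster emitted in the marker panel (a
#'   subset of the true signature genes).
#' @param program_tfs_per_cluster,program_targets_per_tf,program_coefficient,program_noise_sd
#'   planted linear regulatory program (0 TFs disables it).
#' @param seed integer seed; a fixed seed makes the fixture bitwise
#'   reproducible.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(n_clusters = 3, cells_per_cluster = 30,
                              n_signature_genes = 40, n_housekeeping = 50,
                              n_noise_genes = 100, elevation = 3,
                              baseline_log2 = 1, housekeeping_log2 = 6,
                              noise_log2 = -2, noise_sd = 0.3,
                              batch_scale = c(1, 1.5), n_markers = 5,
                              program_tfs_per_cluster = 0,
                              program_targets_per_tf = 5,
                              program_coefficient = 1,
                              program_noise_sd = 0.25,
                              seed = 1) {
  if (n_clusters < 2) stop_fmt("need >= 2 clusters")
  cells_per_cluster <- rep_len(cells_per_cluster, n_clusters)
  if (any(c(cells_per_cluster, n_signature_genes, n_housekeeping,
            n_noise_genes, n_markers) < 0))
    stop_fmt("counts must be non-negative")
  if (any(batch_scale <= 0)) stop_fmt("batch scale factors must be > 0")
  if (n_markers > n_signature_genes)
    stop_fmt("n_markers cannot exceed n_signature_genes")
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Simulate a clustered single-cell expression fixture with ground truth
#'
#' @param cfg a [simulation_config()].
#' @return list with `matrix` (an `ExpressionMatrix`, floored at 0.01),
#'   `labels` (named true cluster per cell), `signature_genes` (list per
#'   cluster), `markers` (a `MarkerPanel`), `association` (gene/cell-type
#'   association table mapping true signatures to synthetic cell types),
#'   `tf_catalog` and `true_edges` (planted program, when configured), and
#'   `config`.
#' @export
simulate_cells <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  with_seed_opt(cfg$seed, {
    k <- cfg$n_clusters
    clusters <- paste0("T", seq_len(k))
    labels <- rep(clusters, cfg$cells_per_cluster)
    n_cells <- length(labels)
    cells <- sprintf("cell_%03d", seq_len(n_cells))
    names(labels) <- cells
    # cells of each cluster alternate across batches so every sample holds
    # every cell type
    batch <- unlist(lapply(cfg$cells_per_cluster, function(nc)
      rep_len(seq_along(cfg$batch_scale), nc)))
    samples <- stats::setNames(paste0("S", batch), cells)

    sig_genes <- lapply(seq_len(k), function(l)
      sprintf("SIG%d_%03d", l, seq_len(cfg$n_signature_genes)))
    names(sig_genes) <- clusters
    hk <- sprintf("HK_%03d", seq_len(cfg$n_housekeeping))
    noise <- sprintf("LOW_%03d", seq_len(cfg$n_noise_genes))
    genes <- c(unlist(sig_genes), hk, noise)

    mean_log2 <- matrix(cfg$baseline_log2, nrow = length(genes),
                        ncol = n_cells, dimnames = list(genes, cells))
    for (l in clusters)
      mean_log2[sig_genes[[l]], labels == l] <-
        cfg$baseline_log2 + cfg$elevation
    mean_log2[hk, ] <- cfg$housekeeping_log2
    mean_log2[noise, ] <- cfg$noise_log2
    vals <- 2^(mean_log2 + matrix(stats::rnorm(length(mean_log2), 0, cfg$noise_sd),
                                  nrow = nrow(mean_log2)))

    tf_catalog <- character(0)
    true_edges <- data.frame(tf = character(0), target = character(0),
                             cluster = character(0), stringsAsFactors = FALSE)
    if (cfg$program_tfs_per_cluster > 0) {
      prog <- lapply(clusters, function(l) {
        tf_ids <- sprintf("TF%s_%02d", sub("^T", "", l),
                          seq_len(cfg$program_tfs_per_cluster))
        tg_ids <- sprintf("TG%s_%02d", sub("^T", "", l),
                          seq_len(cfg$program_tfs_per_cluster *
                                    cfg$program_targets_per_tf))
        inside <- labels == l
        n_in <- sum(inside)
        block <- matrix(2^(cfg$noise_log2 +
                             stats::rnorm(length(c(tf_ids, tg_ids)) * n_cells,
                                          0, cfg$noise_sd)),
                        nrow = length(c(tf_ids, tg_ids)), ncol = n_cells,
                        dimnames = list(c(tf_ids, tg_ids), cells))
        tf_vals <- matrix(stats::rnorm(length(tf_ids) * n_in, mean = 10, sd = 2),
                          nrow = length(tf_ids))
        block[tf_ids, inside] <- pmax(tf_vals, 0.01)
        owner <- rep(tf_ids, each = cfg$program_targets_per_tf)
        for (t_i in seq_along(tg_ids)) {
          tgv <- cfg$program_coefficient * block[owner[t_i], inside] +
            stats::rnorm(n_in, 0, cfg$program_noise_sd * 2)
          block[tg_ids[t_i], inside] <- pmax(tgv, 0.01)
        }
        list(block = block, tfs = tf_ids,
             edges = data.frame(tf = owner, target = tg_ids, cluster = l,
                                stringsAsFactors = FALSE))
      })
      vals <- rbind(vals, do.call(rbind, lapply(prog, `[[`, "block")))
      tf_catalog <- unlist(lapply(prog, `[[`, "tfs"))
      true_edges <- do.call(rbind, lapply(prog, `[[`, "edges"))
    }

    vals <- sweep(vals, 2, cfg$batch_scale[batch], `*`)
    E <- apply_expression_floor(
      expression_matrix(vals, samples), 0.01)

    markers <- marker_panel(lapply(sig_genes, function(g)
      g[seq_len(cfg$n_markers)]))
    association <- do.call(rbind, lapply(clusters, function(l)
      data.frame(gene = sig_genes[[l]], cell_type = paste0("celltype_", l),
                 support_pvalue = 0.001, direction = "positive",
                 stringsAsFactors = FALSE)))
    list(matrix = E, labels = labels, signature_genes = sig_genes,
         markers = markers, association = association,
         tf_catalog = tf_catalog, true_edges = true_edges, config = cfg)
  })
}

#' Simulate a linear regulatory program for network-inference benchmarks
#'
#' Stand-alone cluster-cell matrix matching the linear model assumed by the
#' edge test: TF profiles (and decoy TFs) are i.i.d. standard normal across
#' cells, and each target is the sum of `coefficient` times its TFs plus
#' Gaussian noise. The returned ground-truth edge list is the scoring
#' reference for precision/recall.
#'
#' @param n_cells cells in the cluster (>= 5).
#' @param n_tfs regulating TFs.
#' @param targets_per_tf targets per regulating TF.
#' @param tfs_per_target TFs combined per target (default 1).
#' @param n_decoys decoy TFs with no targets.
#' @param coefficient linear regulatory coefficient.
#' @param noise_sd SD of the target noise (TF profiles have SD 1).
#' @param seed integer seed.
#' @return list with `values` (genes x cells matrix), `tfs` (regulators and
#'   decoys, the TF catalog), `targets`, `true_edges`.
#' @export
simulate_regulatory_program <- function(n_cells = 40, n_tfs = 1,
                                        targets_per_tf = 5,
                                        tfs_per_target = 1, n_decoys = 5,
                                        coefficient = 1, noise_sd = 0.25,
                                        seed = NULL) {
  if (n_cells < 5) stop_fmt("need >= 5 cells")
  if (tfs_per_target > n_tfs)
    stop_fmt("more TFs per target than TFs available")
  with_seed_opt(seed, {
    tf_ids <- sprintf("TF_%02d", seq_len(n_tfs))
    decoy_ids <- if (n_decoys > 0) sprintf("DECOY_%02d", seq_len(n_decoys))
                 else character(0)
    n_targets <- n_tfs * targets_per_tf
    tg_ids <- sprintf("TG_%02d", seq_len(n_targets))
    cells <- sprintf("cell_%03d", seq_len(n_cells))
    tf_m <- matrix(stats::rnorm((n_tfs + n_decoys) * n_cells),
                   nrow = n_tfs + n_decoys,
                   dimnames = list(c(tf_ids, decoy_ids), cells))
    # target t's regulators: its owner TF plus, for multi-TF programs,
    # the following TFs cyclically
    reg <- lapply(seq_len(n_targets), function(t_i) {
      first <- (t_i - 1) %/% targets_per_tf
      tf_ids[(first + seq_len(tfs_per_target) - 1) %% n_tfs + 1]
    })
    tg_m <- t(vapply(seq_len(n_targets), function(t_i) {
      colSums(tf_m[reg[[t_i]], , drop = FALSE]) * coefficient +
        stats::rnorm(n_cells, 0, noise_sd)
    }, numeric(n_cells)))
    dimnames(tg_m) <- list(tg_ids, cells)
    true_edges <- do.call(rbind, lapply(seq_len(n_targets), function(t_i)
      data.frame(tf = reg[[t_i]], target = tg_ids[t_i],
                 stringsAsFactors = FALSE)))
    list(values = rbind(tf_m, tg_m), tfs = c(tf_ids, decoy_ids),
         targets = tg_ids, true_edges = true_edges)
  })
}
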