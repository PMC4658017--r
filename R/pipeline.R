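#' Pipeline configuration
#'
#' All stage parameters with the demonstration defaults: expression filter
#' theta = 5 in n_min = 2 cells, specificity tau_min = 0.7, average linkage
#' on centered Pearson distance with gamma = 0 singletons (or a fixed
#' `threshold` / `k`), Welch/Wilcoxon switch at group size 5, signature
#' metrics delta = 80, alpha = 2, eta = 0.85, TF selection p < 0.05, target
#' selection p < 0.01, edge cutoff S < 0.05. Unknown keys are rejected.
#'
#' @param ... named parameter overrides.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    floor = 0.01, theta = 5, n_min = 2, tau_min = 0.7,
    linkage = "average", metric = "centered_pearson",
    threshold = NULL, k = NULL, gamma = 0, perm_B = 0,
    min_parametric_n = 5, de_alpha = 0.05, de_use = "q",
    delta = 80, alpha = 2, eta = 0.85, p_candidate = 0.05,
    p_tf = 0.05, p_target = 0.01, cutoff = 0.05,
    top_n = 100, validate_r = 0, validate_frac = 0.8,
    trn_cluster = NULL, seed = 1)
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == "")))
    stop_fmt("all configuration overrides must be named")
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop_fmt("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "PipelineConfig")
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop_fmt("stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full profiling pipeline
#'
#' Executes, in order: expression flooring, gene pre-filtering, per-sample
#' z-score normalization, QC summaries, hierarchical clustering (with
#' optional permutation significance), per-cluster differential expression,
#' and -- when the corresponding inputs are given -- cell-type enrichment,
#' marker-based validation, signature prediction (for each cell type mapped
#' to its best-AUC cluster) with optional subsampling validation, and
#' regulatory-network inference plus TF importance ranking. Every stage
#' writes its TSV outputs into `out_dir` and a `manifest.json` records
#' parameters, seed and stage status; identical config and seed reproduce
#' the outputs byte for byte.
#'
#' @param inputs named list: `matrix` + `metadata` (TSV paths) or `E` (an
#'   `ExpressionMatrix`); optional `gene_sets` (path),
#'   `gene_sets_format` ("gmt" or "association_table"), `markers` (path or
#'   `MarkerPanel`), `tf_catalog` (path or character vector).
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param stages stages to run after pre-processing; subset of
#'   `c("qc", "cluster", "de", "enrich", "validate_markers", "signature",
#'   "trn")`.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), out_dir,
                         stages = c("qc", "cluster", "de", "enrich",
                                    "validate_markers", "signature", "trn")) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (length(stages) > 0) stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "scpipeline",
                   version = as.character(utils::packageVersion("scpipeline")),
                   seed = config$seed,
                   parameters = config[!vapply(config, is.null, logical(1))],
                   stages = list())
  done <- function(stage, files) {
    manifest$stages[[stage]] <<- list(status = "ok", outputs = files)
  }
  res <- list()

  E <- stage_try("input", {
    if (!is.null(inputs$E)) inputs$E
    else read_expression_matrix(inputs$matrix, inputs$metadata)
  })
  E <- apply_expression_floor(E, config$floor)
  if ("trn" %in% stages && is.null(inputs$tf_catalog))
    stop_fmt("stage 'trn' requested but no `tf_catalog` input was given")

  pf <- stage_try("prefilter",
                  prefilter(E, config$theta, config$n_min, config$tau_min))
  write_tsv(as.data.frame(pf$report), file.path(out_dir, "prefilter_report.tsv"))
  write_expression_matrix(pf$matrix,
                          file.path(out_dir, "filtered_matrix.tsv"),
                          file.path(out_dir, "filtered_metadata.tsv"))
  done("prefilter", c("prefilter_report.tsv", "filtered_matrix.tsv"))
  res$prefilter <- pf
  Ef <- pf$matrix

  Z <- stage_try("normalize", zscore_normalize(Ef))
  write_tsv(data.frame(gene_id = rownames(Z), Z, check.names = FALSE),
            file.path(out_dir, "normalized_matrix.tsv"))
  done("normalize", "normalized_matrix.tsv")
  res$Z <- Z

  if ("qc" %in% stages && length(sample_labels(Ef)) >= 2) {
    qc <- stage_try("qc", qc_summary(Ef))
    write_tsv(qc$ma, file.path(out_dir, "qc_ma.tsv"))
    write_tsv(qc$qq, file.path(out_dir, "qc_qq.tsv"))
    write_tsv(qc$cell_correlation, file.path(out_dir, "qc_cell_correlation.tsv"))
    done("qc", c("qc_ma.tsv", "qc_qq.tsv", "qc_cell_correlation.tsv"))
    res$qc <- qc
  }

  A <- NULL
  if ("cluster" %in% stages) {
    A <- stage_try("cluster", {
      D <- cell_distance_matrix(Z, config$metric)
      hierarchical_clusters(D, config$linkage, threshold = config$threshold,
                            k = config$k, gamma = config$gamma)
    })
    write_tsv(data.frame(cell_id = names(A$labels), cluster = unname(A$labels)),
              file.path(out_dir, "clusters.tsv"))
    write_tsv(data.frame(merge = seq_along(A$heights), height = A$heights),
              file.path(out_dir, "merge_heights.tsv"))
    files <- c("clusters.tsv", "merge_heights.tsv")
    if (config$perm_B >= 20 && A$k >= 2) {
      sig <- stage_try("cluster", permutation_significance(
        Z, A, B = config$perm_B, seed = config$seed,
        linkage = config$linkage, metric = config$metric))
      write_tsv(data.frame(statistic = sig$statistic, null_mean = sig$null_mean,
                           null_sd = sig$null_sd, p_normal = sig$p_normal,
                           p_empirical = sig$p_empirical, B = sig$B),
                file.path(out_dir, "cluster_significance.tsv"))
      files <- c(files, "cluster_significance.tsv")
      res$cluster_significance <- sig
    }
    done("cluster", files)
    res$clusters <- A
  }

  de <- NULL
  if ("de" %in% stages) {
    if (is.null(A)) stop_fmt("stage 'de' needs the cluster stage")
    de <- stage_try("de",
      cluster_differential_expression(Z, A, config$min_parametric_n))
    write_tsv(as.data.frame(de), file.path(out_dir, "de.tsv"))
    done("de", "de.tsv")
    res$de <- de
  }

  if ("enrich" %in% stages && !is.null(inputs$gene_sets)) {
    enr <- stage_try("enrich", {
      sets <- read_gene_sets(inputs$gene_sets,
                             inputs$gene_sets_format %||% "association_table")
      lists <- de_gene_sets(de, config$de_alpha, config$de_use)
      lists <- lists[lengths(lists) > 0]
      celltype_enrichment(lists, sets, rownames(Ef$values))
    })
    write_tsv(as.data.frame(enr), file.path(out_dir, "enrichment.tsv"))
    done("enrich", "enrichment.tsv")
    res$enrichment <- enr
  }

  panel <- NULL
  if (!is.null(inputs$markers))
    panel <- if (inherits(inputs$markers, "MarkerPanel")) inputs$markers
             else read_marker_panel(inputs$markers)

  mapping <- NULL
  if ("validate_markers" %in% stages && !is.null(panel)) {
    val <- stage_try("validate_markers", {
      do.call(rbind, lapply(names(panel$markers), function(ct) {
        rk <- aggregate_marker_ranks(Ef, panel$markers[[ct]])
        do.call(rbind, lapply(sort(unique(A$labels)), function(cl)
          data.frame(cell_type = ct, cluster = cl,
                     auc = marker_validation_auc(rk, cluster_cells(A, cl)),
                     stringsAsFactors = FALSE)))
      }))
    })
    write_tsv(val, file.path(out_dir, "marker_validation.tsv"))
    done("validate_markers", "marker_validation.tsv")
    res$marker_validation <- val
    # each cell type maps to its best-AUC cluster
    mapping <- do.call(rbind, lapply(split(val, val$cell_type), function(d)
      d[which.max(d$auc), c("cell_type", "cluster")]))
  }

  if ("signature" %in% stages && !is.null(panel)) {
    if (is.null(mapping))
      stop_fmt("stage 'signature' needs the validate_markers stage")
    sig_res <- stage_try("signature", {
      lapply(seq_len(nrow(mapping)), function(i) {
        ct <- mapping$cell_type[i]; cl <- mapping$cluster[i]
        fit <- predict_signature_genes(
          Ef, A, cl, de, panel$markers[[ct]], Z = Z,
          p_candidate = config$p_candidate, seed = config$seed,
          delta = config$delta, alpha = config$alpha, eta = config$eta)
        cbind(cell_type = ct, cluster = cl,
              merge(fit$scores, attr(fit, "metrics")[, c("gene_id", "mc", "mu", "mt", "ms")],
                    by = "gene_id", sort = FALSE))
      })
    })
    sig_tab <- do.call(rbind, sig_res)
    sig_tab <- sig_tab[order(sig_tab$cluster, -sig_tab$theta, sig_tab$gene_id), ]
    write_tsv(sig_tab, file.path(out_dir, "signature.tsv"))
    files <- "signature.tsv"
    if (config$validate_r >= 2) {
      sv <- stage_try("signature", {
        do.call(rbind, lapply(seq_len(nrow(mapping)), function(i) {
          cbind(cluster = mapping$cluster[i], subsampling_validation(
            Ef, Z, A, mapping$cluster[i], panel$markers[[mapping$cell_type[i]]],
            r = config$validate_r, frac = config$validate_frac,
            top_n = config$top_n, seed = config$seed))
        }))
      })
      write_tsv(sv, file.path(out_dir, "signature_validation.tsv"))
      files <- c(files, "signature_validation.tsv")
      res$signature_validation <- sv
    }
    done("signature", files)
    res$signature <- sig_tab
  }

  if ("trn" %in% stages) {
    trn <- stage_try("trn", {
      catalog <- if (is.character(inputs$tf_catalog)) {
        if (length(inputs$tf_catalog) == 1 && file.exists(inputs$tf_catalog))
          read_tf_catalog(inputs$tf_catalog)
        else inputs$tf_catalog
      } else stop_fmt("`tf_catalog` must be a path or character vector")
      cl <- config$trn_cluster %||% sort(unique(A$labels))[1]
      metrics <- compute_signature_metrics(Ef, A, cl, de, Z = Z,
                                           delta = config$delta,
                                           alpha = config$alpha,
                                           eta = config$eta)
      cand <- select_candidates(de, metrics, cl, catalog,
                                config$p_tf, config$p_target)
      # z-scored values: per-sample standardization removes batch scale
      # factors that would otherwise correlate all within-cluster profiles
      net <- infer_first_order_edges(
        Z[, cluster_cells(A, cl), drop = FALSE],
        cand$tfs, cand$targets, config$cutoff)
      list(cluster = cl, candidates = cand, network = net)
    })
    write_tsv(trn$network$edges, file.path(out_dir, "trn_edges.tsv"))
    files <- "trn_edges.tsv"
    if (nrow(trn$network$edges) > 0) {
      comp <- main_component(trn$network)
      imp <- node_importance(comp)
      tfs_in <- intersect(trn$candidates$tfs, imp$node)
      write_tsv(as.data.frame(imp), file.path(out_dir, "tf_importance.tsv"))
      files <- c(files, "tf_importance.tsv")
      if (length(tfs_in) >= 2) {
        ranking <- rank_transcription_factors(imp, tfs_in)
        diag <- metric_diagnostics(imp, tfs_in)
        write_tsv(ranking, file.path(out_dir, "tf_ranking.tsv"))
        write_tsv(diag, file.path(out_dir, "metric_diagnostics.tsv"))
        files <- c(files, "tf_ranking.tsv", "metric_diagnostics.tsv")
        trn$ranking <- ranking
        trn$diagnostics <- diag
      }
      trn$importance <- imp
    }
    done("trn", files)
    res$trn <- trn
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
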