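#' Common-gene metric
#'
#' mc = 1 when the gene is expressed (value >= `theta_expr`) in at least
#' `delta` percent of the cluster's cells; using a percentage rather than all
#' cells tolerates intra-cluster heterogeneity. Defaults delta = 80,
#' theta_expr = 5 (the pre-filter abundance threshold; one "expressed"
#' definition throughout).
#'
#' @param E an `ExpressionMatrix` (or genes x cells matrix).
#' @param cluster_cells character vector of the cluster's cell IDs.
#' @param delta percent of cluster cells required, in (0, 100].
#' @param theta_expr abundance threshold defining "expressed".
#' @return named 0/1 vector per gene.
#' @export
common_gene_metric <- function(E, cluster_cells, delta = 80, theta_expr = 5) {
  if (delta <= 0 || delta > 100) stop_fmt("`delta` must be in (0, 100]")
  v <- as_values_matrix(E)
  if (length(cluster_cells) == 0) stop_fmt("empty cluster")
  need <- ceiling(delta / 100 * length(cluster_cells))
  cnt <- rowSums(v[, cluster_cells, drop = FALSE] >= theta_expr)
  stats::setNames(as.numeric(cnt >= need), rownames(v))
}

#' Unique-gene metric
#'
#' mu = 1 when the gene's mean expression over the cluster's cells is at
#' least `alpha` times the `eta`-quantile of its expression over all other
#' cells; the quantile (linear interpolation) rather than the maximum
#' tolerates a few exceptionally high outliers. Defaults alpha = 2,
#' eta = 0.85.
#'
#' @inheritParams common_gene_metric
#' @param alpha fold requirement (> 0).
#' @param eta outside-cell quantile in (0, 1).
#' @return named 0/1 vector per gene.
#' @export
unique_gene_metric <- function(E, cluster_cells, alpha = 2, eta = 0.85) {
  if (alpha <= 0) stop_fmt("`alpha` must be > 0")
  if (eta <= 0 || eta >= 1) stop_fmt("`eta` must be in (0, 1)")
  v <- as_values_matrix(E)
  out_cells <- setdiff(colnames(v), cluster_cells)
  if (length(out_cells) == 0) stop_fmt("no cells outside the cluster")
  mu_in <- rowMeans(v[, cluster_cells, drop = FALSE])
  q_out <- apply(v[, out_cells, drop = FALSE], 1, stats::quantile,
                 probs = eta, names = FALSE)
  stats::setNames(as.numeric(mu_in >= alpha * q_out), rownames(v))
}

#' Test-statistic metric
#'
#' Normalized, smoothed differential-expression evidence:
#' mt_i = -log(p_i) / max_j(-log(p_j)) over the cluster's tested genes, so
#' the gene with the smallest p attains mt = 1. All p = 1 yields all mt = 0.
#' p-values are floored at 1e-300 before the log.
#'
#' @param p named vector of per-gene p-values for one cluster.
#' @return named vector of mt values in \[0, 1\].
#' @export
test_statistic_metric <- function(p) {
  if (any(p <= 0 | p > 1)) stop_fmt("p-values must be in (0, 1]")
  nl <- -log(pmax(p, 1e-300))
  mx <- max(nl)
  if (mx == 0) return(stats::setNames(rep(0, length(p)), names(p)))
  nl / mx
}

#' Synthetic-profile similarity metric
#'
#' The cluster's synthetic reference profile X* is the indicator vector over
#' all cells (1 inside the cluster, 0 outside), encoding "selectively
#' expressed in this cluster". ms_i = (1 + rho) / 2 where rho is the Pearson
#' correlation between gene i's full-cohort profile and X*; a constant gene
#' profile is assigned rho = 0, ms = 0.5.
#'
#' @param Z genes x cells matrix (typically z-scores) or `ExpressionMatrix`.
#' @param cluster_cells the cluster's cell IDs; needs >= 2 cells inside and
#'   >= 2 outside.
#' @return named vector of ms values in \[0, 1\].
#' @export
synthetic_profile_similarity <- function(Z, cluster_cells) {
  v <- as_values_matrix(Z)
  ind <- as.numeric(colnames(v) %in% cluster_cells)
  if (sum(ind) < 2 || sum(1 - ind) < 2)
    stop_fmt("need >= 2 cells inside and outside the cluster")
  rho <- suppressWarnings(as.vector(stats::cor(t(v), ind)))
  rho[is.na(rho)] <- 0
  stats::setNames((1 + rho) / 2, rownames(v))
}

#' All four signature metrics for one cluster
#'
#' @param E an `ExpressionMatrix` (abundance scale; used for mc and mu).
#' @param A a `ClusterAssignment`.
#' @param cluster cluster label.
#' @param de a `DEResult` providing the cluster's p-values (for mt).
#' @param Z optional normalized matrix for the profile-similarity metric
#'   (defaults to the abundance values).
#' @param delta,theta_expr,alpha,eta metric parameters, see the individual
#'   metric functions.
#' @return data frame of class `SignatureMetrics` with gene_id, mc, mu, mt,
#'   ms and the cluster's p-value.
#' @export
compute_signature_metrics <- function(E, A, cluster, de, Z = NULL,
                                      delta = 80, theta_expr = 5,
                                      alpha = 2, eta = 0.85) {
  cc <- cluster_cells(A, cluster)
  dcl <- de[de$cluster == cluster, ]
  p <- stats::setNames(dcl$p, dcl$gene_id)
  genes <- rownames(as_values_matrix(E))
  if (!all(genes %in% names(p)))
    stop_fmt("DE results missing for some genes of cluster '%s'", cluster)
  p <- p[genes]
  out <- data.frame(
    gene_id = genes,
    mc = unname(common_gene_metric(E, cc, delta, theta_expr)),
    mu = unname(unique_gene_metric(E, cc, alpha, eta)),
    mt = unname(test_statistic_metric(p)),
    ms = unname(synthetic_profile_similarity(Z %||% E, cc)),
    p = unname(p),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("SignatureMetrics", class(out))
  out
}

#' Build a class-balanced training set for signature prediction
#'
#' Positives are the known markers of the cell type; the negative pool holds
#' genes that are non-differentially-expressed (p >= `p_nonde_min`) and
#' neither common nor unique for the cluster (mc = mu = 0). Negatives are
#' sampled from the pool without replacement to match the number of
#' positives (the whole pool, with a warning, when it is smaller).
#'
#' @param metrics a `SignatureMetrics` data frame (with the p column).
#' @param known_markers character vector of marker gene IDs (>= 3 present).
#' @param p_nonde_min minimum p defining "non-DE" (default 0.05).
#' @param seed integer seed for the negative sampling (NULL uses the ambient
#'   RNG stream).
#' @return data frame with gene_id and label (1 positive / 0 negative).
#' @export
build_training_set <- function(metrics, known_markers, p_nonde_min = 0.05,
                               seed = NULL) {
  pos <- intersect(known_markers, metrics$gene_id)
  if (length(pos) < 3) stop_fmt("need >= 3 known markers present in the matrix")
  pool <- metrics$gene_id[metrics$p >= p_nonde_min & metrics$mc == 0 &
                            metrics$mu == 0]
  pool <- setdiff(pool, pos)
  if (length(pool) == 0) stop_fmt("empty negative pool")
  neg <- if (length(pool) <= length(pos)) {
    warn_fmt("negative pool (%d) smaller than positives (%d); using all of it",
             length(pool), length(pos))
    pool
  } else {
    with_seed_opt(seed, sample(pool, length(pos)))
  }
  data.frame(gene_id = c(pos, neg),
             label = rep(c(1, 0), c(length(pos), length(neg))),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Ridge-penalized logistic regression by Newton/IRLS with step halving.
# The penalty (lambda * ||beta||^2, intercept unpenalized) guarantees a
# finite optimum on separable training sets.
ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 200, tol = 1e-10) {
  pen <- c(0, rep(lambda, ncol(X) - 1))
  obj <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta))) + sum(pen * b^2)
  }
  beta <- rep(0, ncol(X))
  f <- obj(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X, X * w) + 2 * diag(pen, ncol(X))
    g <- drop(crossprod(X, y - mu)) - 2 * pen * beta
    step <- solve(H, g)
    t <- 1
    repeat {
      cand <- beta + t * step
      fc <- obj(cand)
      if (fc <= f + 1e-12 || t < 1e-8) break
      t <- t / 2
    }
    moved <- max(abs(cand - beta))
    beta <- cand; f <- fc
    if (moved < tol) return(list(coefficients = beta, iterations = it,
                                 converged = TRUE))
  }
  stop_fmt("logistic fit did not converge in %d iterations (max |grad| = %.3g)",
           max_iter, max(abs(g)))
}

#' Fit the logistic signature-ranking model and score candidate genes
#'
#' Maximum-likelihood logistic regression of the training labels on the four
#' metrics (mc, mu, mt, ms), with a small ridge penalty (default
#' lambda = 1e-4) so the fit exists even when marker-based training sets are
#' linearly separable. Every candidate gene receives the signature
#' probability theta from the fitted model, plus a normalized prediction
#' score (theta min-max rescaled to \[0, 1\] over the candidates).
#'
#' @param training data frame from [build_training_set()].
#' @param metrics a `SignatureMetrics` data frame covering the training and
#'   candidate genes.
#' @param candidates character vector of genes to score (default: all genes
#'   in `metrics`; the pipeline passes the cluster's DE genes).
#' @param lambda ridge penalty.
#' @return list of class `signature_model` with `model` (coefficients beta0,
#'   beta_c, beta_u, beta_t, beta_s; training sizes) and `scores` (data frame
#'   gene_id, theta, normalized_score, ranked by descending theta).
#' @export
fit_signature_model <- function(training, metrics, candidates = NULL,
                                lambda = 1e-4) {
  if (length(unique(training$label)) < 2)
    stop_fmt("training set needs both classes")
  feat <- function(genes) {
    m <- metrics[match(genes, metrics$gene_id), c("mc", "mu", "mt", "ms")]
    if (anyNA(m)) stop_fmt("metrics missing for some genes")
    cbind(intercept = 1, as.matrix(m))
  }
  fit <- ridge_logistic(feat(training$gene_id), training$label, lambda)
  beta <- stats::setNames(fit$coefficients,
                          c("beta0", "beta_c", "beta_u", "beta_t", "beta_s"))
  candidates <- candidates %||% metrics$gene_id
  theta <- drop(stats::plogis(feat(candidates) %*% fit$coefficients))
  rng <- range(theta)
  nscore <- if (diff(rng) == 0) rep(1, length(theta)) else
    (theta - rng[1]) / diff(rng)
  scores <- data.frame(gene_id = candidates, theta = theta,
                       normalized_score = nscore,
                       stringsAsFactors = FALSE, row.names = NULL)
  scores <- scores[order(-scores$theta, scores$gene_id), ]
  rownames(scores) <- NULL
  structure(list(model = list(coefficients = beta,
                              n_positive = sum(training$label == 1),
                              n_negative = sum(training$label == 0),
                              iterations = fit$iterations, lambda = lambda),
                 scores = scores),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  co <- x$model$coefficients
  cat(sprintf("signature_model: %d+/%d- training genes; coefficients %s; %d candidates scored\n",
              x$model$n_positive, x$model$n_negative,
              paste(sprintf("%s=%.2f", names(co), co), collapse = " "),
              nrow(x$scores)))
  invisible(x)
}

# One-cluster DE p-values (Welch when both groups exceed min_parametric_n,
# else Wilcoxon), used where the full DEResult battery is not needed.
de_p_for_cluster <- function(m, in_cells, min_parametric_n = 5) {
  in_idx <- which(colnames(m) %in% in_cells)
  n1 <- length(in_idx); n2 <- ncol(m) - n1
  p <- if (n1 > min_parametric_n && n2 > min_parametric_n) {
    welch_greater_rows(m, in_idx)
  } else {
    vapply(seq_len(nrow(m)), function(i)
      two_group_test(m[i, in_idx], m[i, -in_idx], "wilcoxon")$p.value,
      numeric(1))
  }
  stats::setNames(pmax(p, 1e-300), rownames(m))
}

#' Signature prediction for one cluster, end to end
#'
#' Computes the four metrics, builds the marker-based training set, fits the
#' logistic ranking model, and scores the cluster's differentially expressed
#' genes (p < `p_candidate`).
#'
#' @inheritParams compute_signature_metrics
#' @param markers known marker genes of the cluster's cell type.
#' @param p_candidate p cutoff defining the candidate genes scored by the
#'   model (default 0.05).
#' @param seed seed for the training-set sampling.
#' @param ... passed to [compute_signature_metrics()].
#' @return a `signature_model` (see [fit_signature_model()]) with the metrics
#'   attached as attribute `"metrics"`.
#' @export
predict_signature_genes <- function(E, A, cluster, de, markers, Z = NULL,
                                    p_candidate = 0.05, seed = NULL, ...) {
  metrics <- compute_signature_metrics(E, A, cluster, de, Z = Z, ...)
  training <- build_training_set(metrics, markers, seed = seed)
  candidates <- metrics$gene_id[metrics$p < p_candidate]
  if (length(candidates) == 0) stop_fmt("no candidate (DE) genes to score")
  fit <- fit_signature_model(training, metrics, candidates)
  attr(fit, "metrics") <- metrics
  fit
}

#' Repeated random subsampling validation of signature prediction
#'
#' Each repetition samples `frac` of the cluster's cells, re-runs signature
#' prediction with the held-out cells excluded, takes the `top_n` predicted
#' signature genes, and trains one linear-margin binary classifier (support
#' vector machine, linear kernel) per other cluster on `frac` of both
#' clusters' cells restricted to those genes; the reported accuracy is
#' measured on the held-out cells. Mean and standard error over `r`
#' repetitions per cluster pair.
#'
#' @param E an `ExpressionMatrix` (abundance scale, for mc/mu).
#' @param Z normalized genes x cells matrix used for ms and classification.
#' @param A a `ClusterAssignment`.
#' @param cluster the cluster whose signature is validated.
#' @param markers known markers for the cluster's cell type.
#' @param r repetitions (>= 2, default 100).
#' @param frac training fraction (default 0.8).
#' @param top_n signature size used for classification (default 100).
#' @param seed integer seed; fixed seed gives a bitwise-reproducible result.
#' @param min_parametric_n Welch/Wilcoxon switch for the re-run DE.
#' @return data frame with other_cluster, mean_accuracy, se; the r x
#'   (k - 1) accuracy matrix is attached as attribute `"accuracy"`.
#' @export
subsampling_validation <- function(E, Z, A, cluster, markers, r = 100,
                                   frac = 0.8, top_n = 100, seed = NULL,
                                   min_parametric_n = 5) {
  if (r < 2) stop_fmt("`r` must be >= 2")
  v <- as_values_matrix(E)
  Zm <- as_values_matrix(Z)
  cl_cells <- cluster_cells(A, cluster)
  n_tr <- floor(frac * length(cl_cells))
  if (n_tr < 2 || n_tr >= length(cl_cells))
    stop_fmt("cluster '%s' too small to hold out cells at frac = %g",
             cluster, frac)
  others <- setdiff(sort(unique(A$labels)), cluster)
  acc <- matrix(NA_real_, nrow = r, ncol = length(others),
                dimnames = list(NULL, others))
  with_seed_opt(seed, {
    for (rep_i in seq_len(r)) {
      tr_l <- sample(cl_cells, n_tr)
      te_l <- setdiff(cl_cells, tr_l)
      keep <- setdiff(colnames(v), te_l)
      p <- de_p_for_cluster(Zm[, keep, drop = FALSE], tr_l, min_parametric_n)
      metrics <- data.frame(
        gene_id = rownames(v),
        mc = unname(common_gene_metric(v[, keep, drop = FALSE], tr_l)),
        mu = unname(unique_gene_metric(v[, keep, drop = FALSE], tr_l)),
        mt = unname(test_statistic_metric(p)),
        ms = unname(synthetic_profile_similarity(Zm[, keep, drop = FALSE], tr_l)),
        p = unname(p), stringsAsFactors = FALSE)
      training <- build_training_set(metrics, markers)
      candidates <- metrics$gene_id[metrics$p < 0.05]
      # degenerate subsample with no DE genes: rank everything instead
      if (length(candidates) == 0) candidates <- metrics$gene_id
      fit <- fit_signature_model(training, metrics, candidates)
      sig <- utils::head(fit$scores$gene_id, top_n)
      for (co in others) {
        co_cells <- cluster_cells(A, co)
        n_tr_o <- max(2, floor(frac * length(co_cells)))
        if (n_tr_o >= length(co_cells))
          stop_fmt("cluster '%s' too small to hold out cells", co)
        tr_o <- sample(co_cells, n_tr_o)
        te_o <- setdiff(co_cells, tr_o)
        xtr <- t(Zm[sig, c(tr_l, tr_o), drop = FALSE])
        ytr <- factor(rep(c(cluster, co), c(length(tr_l), length(tr_o))))
        xte <- t(Zm[sig, c(te_l, te_o), drop = FALSE])
        yte <- factor(rep(c(cluster, co), c(length(te_l), length(te_o))),
                      levels = levels(ytr))
        fitsvm <- e1071::svm(xtr, ytr, kernel = "linear", scale = FALSE)
        acc[rep_i, co] <- mean(stats::predict(fitsvm, xte) == yte)
      }
    }
  })
  out <- data.frame(other_cluster = others,
                    mean_accuracy = colMeans(acc),
                    se = apply(acc, 2, stats::sd) / sqrt(r),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "accuracy") <- acc
  out
}
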