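metric_matrix <- function() {
  # 10-cell cluster (k1..k10) + 10 outside cells (o1..o10)
  cells <- c(paste0("k", 1:10), paste0("o", 1:10))
  v <- rbind(
    gA = c(rep(8, 8), 0, 0, rep(0.5, 10)),       # expressed in 8/10 cluster cells
    gB = c(rep(8, 7), 0, 0, 0, rep(0.5, 10)),    # 7/10
    gC = c(rep(10, 10), 1, 1, 1, 1, 1, 1, 1, 1, 1, 4)) # outside 0.85-q = 2.65
  colnames(v) <- cells
  expression_matrix(v, stats::setNames(rep(c("S1"), 20), cells))
}

test_that("common-gene metric counts expressing cluster cells against delta", {
  E <- metric_matrix()
  cl <- paste0("k", 1:10)
  mc <- common_gene_metric(E, cl, delta = 80, theta_expr = 5)
  expect_equal(unname(mc[c("gA", "gB")]), c(1, 0))
  # delta = 100 requires every cell
  expect_equal(unname(common_gene_metric(E, cl, delta = 100)["gC"]), 1)
  expect_equal(unname(common_gene_metric(E, cl, delta = 100)["gA"]), 0)
  expect_error(common_gene_metric(E, character(0)), "empty cluster")
})

test_that("unique-gene metric compares the cluster mean to the outside quantile", {
  E <- metric_matrix()
  cl <- paste0("k", 1:10)
  # gC: mean 10 inside; outside values have 0.85-quantile
  q <- unname(stats::quantile(c(rep(1, 9), 4), 0.85))
  expect_equal(unname(unique_gene_metric(E, cl, alpha = 2, eta = 0.85)["gC"]),
               as.numeric(10 >= 2 * q))
  expect_equal(unname(unique_gene_metric(E, cl, alpha = 8, eta = 0.85)["gC"]),
               as.numeric(10 >= 8 * q))
  # hand case: cluster mean 10, all outside <= 4 at alpha 2 -> unique
  v <- rbind(g = c(rep(10, 4), c(4, 4, 3, 2, 1, 0)))
  colnames(v) <- c(paste0("k", 1:4), paste0("o", 1:6))
  E2 <- expression_matrix(v, stats::setNames(rep("S1", 10), colnames(v)))
  expect_equal(unname(unique_gene_metric(E2, paste0("k", 1:4))["g"]), 1)
  expect_error(unique_gene_metric(E2, colnames(v)), "no cells outside")
})

test_that("test-statistic metric is -log p normalized to the cluster maximum", {
  p <- c(g1 = 0.01, g2 = 0.1)
  expect_equal(unname(test_statistic_metric(p)), c(1, 0.5))
  expect_equal(unname(test_statistic_metric(c(a = 1, b = 1))), c(0, 0))
  p2 <- c(a = 1e-8, b = 0.3, c = 1)
  mt <- test_statistic_metric(p2)
  expect_equal(unname(mt["a"]), 1)
  expect_equal(unname(mt["c"]), 0)
  expect_true(all(mt >= 0 & mt <= 1))
})

test_that("synthetic-profile similarity is the rescaled indicator correlation", {
  cells <- paste0("c", 1:6)
  cl <- cells[1:3]
  ind <- c(1, 1, 1, 0, 0, 0)
  v <- rbind(g1 = ind,                       # exactly the indicator
             g2 = c(0, 0, 0, 5, 5, 5),      # only outside, uniform
             g3 = c(3, 1, 4, 0.5, 0.2, 0.1),
             g4 = rep(2, 6))                # constant
  colnames(v) <- cells
  ms <- synthetic_profile_similarity(v, cl)
  expect_equal(unname(ms["g1"]), 1)
  expect_lt(ms["g2"], 0.5)
  expect_equal(unname(ms["g3"]), (1 + stats::cor(v["g3", ], ind)) / 2,
               tolerance = 1e-12)
  expect_equal(unname(ms["g4"]), 0.5)
  expect_error(synthetic_profile_similarity(v, cells), "outside")
})

test_that("training sets are marker-positive, metric-negative and seeded", {
  metrics <- data.frame(
    gene_id = sprintf("g%02d", 1:40),
    mc = rep(c(1, 0), c(10, 30)),
    mu = 0, mt = 0.1, ms = 0.5,
    p = rep(c(0.001, 0.5), c(10, 30)))
  tr <- build_training_set(metrics, c("g01", "g02", "g03", "g04"), seed = 3)
  expect_equal(sum(tr$label == 1), 4)
  expect_equal(sum(tr$label == 0), 4)
  # negatives come from the non-DE, non-common, non-unique pool
  neg <- tr$gene_id[tr$label == 0]
  expect_true(all(metrics$p[match(neg, metrics$gene_id)] >= 0.05))
  expect_true(all(metrics$mc[match(neg, metrics$gene_id)] == 0))
  tr2 <- build_training_set(metrics, c("g01", "g02", "g03", "g04"), seed = 3)
  expect_identical(tr, tr2)
  expect_error(build_training_set(metrics, c("g01", "g02")), ">= 3")
  # pool smaller than positives: take the whole pool with a warning
  m2 <- metrics[c(1:10, 11:12), ]
  expect_warning(build_training_set(m2, paste0("g0", 1:9), seed = 1),
                 "negative pool")
})

test_that("logistic ranking respects metric dominance and separable training", {
  fx <- planted_fixture(seed = 7)
  de <- cluster_differential_expression(fx$Z, fx$A)
  cl <- matched_cluster(fx$A, fx$sim$labels, "T1")
  fit <- predict_signature_genes(fx$E, fx$A, cl, de,
                                 fx$sim$markers$markers$T1, Z = fx$Z, seed = 3)
  co <- fit$model$coefficients
  expect_true(all(is.finite(co)))
  expect_true(all(co[c("beta_c", "beta_u", "beta_t", "beta_s")] > 0))

  # with all-positive coefficients, theta is monotone in each metric
  b <- unname(co)
  theta_of <- function(m) stats::plogis(b[1] + sum(b[2:5] * m))
  base <- c(0, 0, 0.4, 0.5)
  for (j in 1:4) {
    up <- base; up[j] <- base[j] + 0.5
    expect_gt(theta_of(up), theta_of(base))
  }

  # theta ranking separates planted signatures from the background
  metrics <- attr(fit, "metrics")
  all_fit <- fit_signature_model(
    build_training_set(metrics, fx$sim$markers$markers$T1, seed = 3), metrics)
  truth <- all_fit$scores$gene_id %in% fx$sim$signature_genes$T1
  r <- rank(all_fit$scores$theta)
  auc <- (sum(r[truth]) - sum(truth) * (sum(truth) + 1) / 2) /
    (sum(truth) * sum(!truth))
  expect_gte(auc, 0.95)
  expect_true(all(fit$scores$normalized_score >= 0 &
                  fit$scores$normalized_score <= 1))
})

test_that("subsampling validation is reproducible and collapses on shuffled labels", {
  fx <- planted_fixture(seed = 7)
  cl <- matched_cluster(fx$A, fx$sim$labels, "T1")
  mk <- fx$sim$markers$markers$T1
  sv1 <- subsampling_validation(fx$E, fx$Z, fx$A, cl, mk, r = 2, top_n = 40,
                                seed = 11)
  sv2 <- subsampling_validation(fx$E, fx$Z, fx$A, cl, mk, r = 2, top_n = 40,
                                seed = 11)
  expect_identical(attr(sv1, "accuracy"), attr(sv2, "accuracy"))
  expect_true(all(sv1$mean_accuracy >= 0 & sv1$mean_accuracy <= 1))

  # shuffled cluster labels carry no signal: accuracy near chance
  Ash <- fx$A
  Ash$labels <- withr::with_seed(4, stats::setNames(sample(Ash$labels),
                                                    names(Ash$labels)))
  Ash$sizes <- table(Ash$labels)
  svs <- subsampling_validation(fx$E, fx$Z, Ash, cl, mk, r = 4, top_n = 40,
                                seed = 11)
  expect_lt(mean(svs$mean_accuracy), 0.75)
})
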