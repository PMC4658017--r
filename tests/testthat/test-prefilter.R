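one_sample_matrix <- function(values, gene = "g1") {
  v <- matrix(values, nrow = length(gene), byrow = TRUE,
              dimnames = list(gene, sprintf("c%d", seq_along(values))))
  expression_matrix(v, stats::setNames(rep("S1", ncol(v)), colnames(v)))
}

test_that("expression filter counts expressing cells per sample", {
  E <- one_sample_matrix(c(5, 5, 0))
  expect_true(expression_filter(E, theta = 5, n_min = 2)["g1", "S1"])
  E2 <- one_sample_matrix(c(4.9, 100, 0))
  expect_false(expression_filter(E2, theta = 5, n_min = 2)["g1", "S1"])
  # rare-cell mode: a single expressing cell suffices at n_min = 1
  E3 <- one_sample_matrix(c(0, 0, 7))
  expect_true(expression_filter(E3, theta = 5, n_min = 1)["g1", "S1"])
  expect_warning(expression_filter(E3, theta = 5, n_min = 10), "no gene can pass")
})

test_that("specificity index matches its defining formula", {
  # expressed in exactly one of q cells -> tau = 1
  expect_equal(unname(specificity_index(one_sample_matrix(c(0, 0, 9, 0)), "S1")), 1)
  # constant gene -> 0 by convention
  expect_equal(unname(specificity_index(one_sample_matrix(c(3, 3, 3)), "S1")), 0)
  # hand evaluation: x = (0, 0.5, 1), tau = (1 + 0.5 + 0) / 2
  expect_equal(unname(specificity_index(one_sample_matrix(c(0, 5, 10)), "S1")), 0.75)
  expect_error(specificity_index(one_sample_matrix(5), "S1"), "fewer than 2")
})

test_that("tau stays in [0,1] and falls as expression spreads across cells", {
  E <- random_expression_matrix(200, 30, n_samples = 1, seed = 42)
  tau <- specificity_index(E, "S1")
  expect_true(all(tau >= 0 & tau <= 1))
  # fixed maximum and minimum, mass spread over more cells => tau falls
  spread <- list(c(10, 0, 0, 0), c(10, 5, 0, 0), c(10, 5, 5, 0))
  taus <- vapply(spread, function(v)
    unname(specificity_index(one_sample_matrix(v), "S1")), numeric(1))
  expect_true(all(diff(taus) < 0))
})

test_that("prefilter sections partition genes and gate on both filters", {
  # g1: passes both in both samples; g2: expressed everywhere (low tau);
  # g3: below theta everywhere; g4: expression filter passes in S1 only
  v <- rbind(g1 = c(9, 0, 0, 8, 0, 0),
             g2 = c(5, 9, 9, 5, 9, 9),   # tau = 0.5 in each sample
             g3 = c(1, 0, 1, 0, 1, 0),
             g4 = c(9, 9, 0, 1, 0, 0))
  colnames(v) <- sprintf("c%d", 1:6)
  E <- expression_matrix(v, stats::setNames(rep(c("S1", "S2"), each = 3),
                                            colnames(v)))
  pf <- prefilter(E, theta = 5, n_min = 1, tau_min = 0.7)
  sec <- stats::setNames(pf$report$section, pf$report$gene_id)
  expect_identical(sec, c(g1 = 1L, g2 = 2L, g3 = 3L, g4 = 4L))
  expect_identical(rownames(pf$matrix$values), "g1")
  expect_identical(pf$report$kept, pf$report$section == 1L)

  # permissive thresholds keep everything
  pf2 <- prefilter(E, theta = 1e-6, n_min = 1, tau_min = 0)
  expect_true(all(pf2$report$kept))
})

test_that("z-score normalization standardizes per sample and is idempotent", {
  E <- random_expression_matrix(50, 12, n_samples = 2, seed = 5)
  Z <- zscore_normalize(E)
  for (s in c("S1", "S2")) {
    zs <- Z[, cells_of_sample(E, s)]
    expect_equal(unname(rowMeans(zs)), rep(0, nrow(zs)), tolerance = 1e-12)
    expect_equal(unname(apply(zs, 1, sd)), rep(1, nrow(zs)), tolerance = 1e-12)
  }
  expect_equal(unclass(zscore_normalize(Z)), unclass(Z), tolerance = 1e-12,
               ignore_attr = TRUE)
  # constant gene maps to zero
  v <- rbind(g1 = c(4, 4, 4), g2 = c(1, 2, 3))
  colnames(v) <- c("c1", "c2", "c3")
  Ec <- expression_matrix(v, stats::setNames(rep("S1", 3), colnames(v)))
  expect_equal(unname(zscore_normalize(Ec)["g1", ]), rep(0, 3))
  # per-sample z-scores are invariant to global sample scale
  v2 <- E$values
  v2[, cells_of_sample(E, "S2")] <- v2[, cells_of_sample(E, "S2")] * 7
  Z2 <- zscore_normalize(expression_matrix(v2, E$samples))
  expect_equal(unclass(Z2), unclass(Z), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("trimmed-mean scaling equalizes cells and resists outliers", {
  E <- random_expression_matrix(40, 6, n_samples = 1, seed = 9)
  En <- trimmed_mean_normalize(E, trim = 0.05)
  tms <- apply(En$values, 2, mean, trim = 0.05)
  expect_equal(max(abs(tms / mean(tms) - 1)), 0, tolerance = 1e-9)

  # scalar-multiple cells collapse to identical columns
  base <- withr::with_seed(2, stats::rlnorm(40))
  v <- cbind(c1 = base, c2 = 3 * base, c3 = 0.5 * base)
  rownames(v) <- sprintf("g%02d", seq_along(base))
  Es <- expression_matrix(v, c(c1 = "S1", c2 = "S1", c3 = "S1"))
  En2 <- trimmed_mean_normalize(Es, trim = 0.1)
  expect_equal(En2$values[, "c1"], En2$values[, "c2"], tolerance = 1e-12)
  expect_equal(En2$values[, "c1"], En2$values[, "c3"], tolerance = 1e-12)

  # trim = 0 is plain mean scaling (hand-checked factor)
  En3 <- trimmed_mean_normalize(Es, trim = 0)
  f <- attr(En3, "scale_factors")
  expect_equal(unname(f["c1"]), mean(colMeans(v)) / mean(v[, "c1"]))

  # a single huge outlier is excluded from a 40-value cell's factor
  vo <- v
  vo[1, "c1"] <- 1e6
  Eo <- expression_matrix(vo, c(c1 = "S1", c2 = "S1", c3 = "S1"))
  f_trim <- attr(trimmed_mean_normalize(Eo, trim = 0.05), "scale_factors")["c1"]
  hand <- mean(sort(vo[, "c1"])[3:38])  # 40 values, floor(40*.05)=2 per tail
  expect_equal(unname(apply(Eo$values, 2, mean, trim = 0.05)["c1"]), hand)
  expect_gt(f_trim, attr(trimmed_mean_normalize(Eo, trim = 0), "scale_factors")["c1"])

  vz <- v; vz[, "c2"] <- 0
  expect_error(trimmed_mean_normalize(
    expression_matrix(vz, Es$samples)), "c2")
})

test_that("QC summaries reproduce the MA definition and cross-sample correlation", {
  # constant genes give exactly controllable sample means
  v <- rbind(g1 = c(4, 4, 1, 1),   # mean1 = 4, mean2 = 1 -> M = 2, A = 1
             g2 = c(2, 2, 2, 2))   # identical -> M = 0
  colnames(v) <- c("a1", "a2", "b1", "b2")
  E <- expression_matrix(v, c(a1 = "S1", a2 = "S1", b1 = "S2", b2 = "S2"))
  qc <- qc_summary(E)
  ma <- qc$ma
  expect_equal(ma$M[ma$gene_id == "g1"], 2)
  expect_equal(ma$A[ma$gene_id == "g1"], 1)
  expect_equal(ma$M[ma$gene_id == "g2"], 0)

  # duplicated cells across samples -> correlation 1, distance 0
  E2 <- random_expression_matrix(30, 4, n_samples = 1, seed = 3)
  v2 <- cbind(E2$values, E2$values)
  colnames(v2) <- c(paste0("a", 1:4), paste0("b", 1:4))
  Ed <- expression_matrix(v2, stats::setNames(rep(c("S1", "S2"), each = 4),
                                              colnames(v2)))
  cc <- qc_summary(Ed)$cell_correlation
  dup <- cc[cc$cell_a == "a2" & cc$cell_b == "b2", ]
  expect_equal(dup$correlation, 1)
  expect_equal(dup$distance, 0, tolerance = 1e-12)

  expect_error(qc_summary(random_expression_matrix(5, 4, 1)), "2 samples")
})
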