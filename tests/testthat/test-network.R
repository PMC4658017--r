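test_that("candidate selection gates TFs on the catalog and DE/commonness", {
  metrics <- data.frame(
    gene_id = c("tf1", "tf2", "tf3", "g1", "g2"),
    mc = c(0, 1, 0, 0, 0), mu = 0, mt = 0.5, ms = 0.5,
    p = c(0.001, 0.2, 0.2, 1e-6, 0.02))
  de <- data.frame(gene_id = metrics$gene_id, cluster = "C1",
                   test = "welch_t", p = metrics$p, q = metrics$p)
  cand <- select_candidates(de, metrics, "C1", c("tf1", "tf2", "tf3"))
  expect_setequal(cand$tfs, c("tf1", "tf2"))  # tf2 in via mc = 1 despite p = 0.2
  expect_setequal(cand$targets, c("tf1", "g1")) # p < 0.01, catalog irrelevant
  expect_warning(select_candidates(de, metrics, "C1", "tf1"), "fewer than 2")
  expect_error(select_candidates(de, metrics, "C1", character(0)), "empty")
})

test_that("conditional regression p-values match lm on a 6-point dataset", {
  x1 <- c(1, 2, 3, 4, 5, 6)
  x2 <- c(2, 1, 4, 3, 6, 5)
  y <- c(1.2, 2.1, 2.9, 4.3, 5.2, 5.8)
  ref <- summary(stats::lm(y ~ x1 + x2))$coefficients
  got <- scpipeline:::coef_p_value(y, x1, x2)
  expect_equal(got$p, ref["x1", "Pr(>|t|)"], tolerance = 1e-12)
  ref1 <- summary(stats::lm(y ~ x1))$coefficients
  got1 <- scpipeline:::coef_p_value(y, x1)
  expect_equal(got1$p, ref1["x1", "Pr(>|t|)"], tolerance = 1e-12)
  expect_equal(got1$coef, unname(ref1["x1", "Estimate"]), tolerance = 1e-12)
})

test_that("planted linear programs are recovered and decoys rejected", {
  pr <- simulate_regulatory_program(n_cells = 40, n_tfs = 1, targets_per_tf = 5,
                                    n_decoys = 5, coefficient = 2,
                                    noise_sd = 0.2, seed = 17)
  net <- infer_first_order_edges(pr$values, pr$tfs, pr$targets, cutoff = 0.05)
  truth <- paste(pr$true_edges$tf, pr$true_edges$target)
  found <- paste(net$edges$tf, net$edges$target)
  expect_true(all(truth %in% found))
  expect_true(all(net$edges$S < 0.05))
  expect_true(all(net$edges$coef_sign[found %in% truth] == 1))

  # null: independent TFs and targets retained at most ~cutoff rate
  pr0 <- simulate_regulatory_program(n_cells = 30, n_tfs = 4,
                                     targets_per_tf = 10, n_decoys = 0,
                                     coefficient = 0, noise_sd = 1, seed = 23)
  net0 <- infer_first_order_edges(pr0$values, pr0$tfs, pr0$targets)
  expect_lte(nrow(net0$edges) / (length(pr0$tfs) * length(pr0$targets)), 0.05)

  # collinear conditioning TFs are skipped with a warning
  vals <- pr$values
  vals <- rbind(vals, TF_COPY = vals["TF_01", ])
  w <- testthat::capture_warnings(
    infer_first_order_edges(vals, c(pr$tfs, "TF_COPY"), pr$targets))
  expect_true(any(grepl("collinear", w)))
  expect_error(infer_first_order_edges(pr$values[, 1:3], pr$tfs, pr$targets),
               ">= 5 cells")
})

test_that("main component picks the largest (then lexicographic) component", {
  edges <- data.frame(
    tf = c("a", "a", "b", "x", "x"),
    target = c("b", "c", "d", "y", "z"), S = 0.01, coef_sign = 1)
  net <- structure(list(edges = edges, tfs = c("a", "b", "x"),
                        targets = c("b", "c", "d", "y", "z"), cutoff = 0.05),
                   class = "RegulatoryNetwork")
  comp <- main_component(net)
  expect_setequal(igraph::V(comp)$name, c("a", "b", "c", "d"))
  # size tie: component holding the smallest node ID wins
  edges2 <- data.frame(tf = c("m", "a"), target = c("n", "b"),
                       S = 0.01, coef_sign = 1)
  net2 <- structure(list(edges = edges2, tfs = c("m", "a"),
                         targets = c("n", "b"), cutoff = 0.05),
                    class = "RegulatoryNetwork")
  expect_setequal(igraph::V(main_component(net2))$name, c("a", "b"))
})

test_that("importance metrics reproduce hand values on canonical graphs", {
  star <- adj_to_graph(rbind(c(0, 1, 1, 1), c(1, 0, 0, 0),
                             c(1, 0, 0, 0), c(1, 0, 0, 0)))
  imp <- node_importance(star)
  ctr <- imp[imp$node == "n01", ]
  leaf <- imp[imp$node == "n02", ]
  expect_equal(ctr$DC, 3)
  expect_equal(ctr$DFC, 1)          # removal leaves 3 singletons
  expect_equal(leaf$DFC, 1 / 3)
  expect_equal(ctr$DCC, 1)          # nothing reaches anything without the hub
  expect_equal(ctr$CC, 1 / 3)

  path <- adj_to_graph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  mid <- node_importance(path)
  b <- mid[mid$node == "n02", ]
  expect_equal(b$CC, 1 / 2)
  expect_equal(b$DDC, 1)
  expect_equal(b$DCC, 1)

  tri <- adj_to_graph(matrix(1, 3, 3) - diag(3))
  t1 <- node_importance(tri)[1, ]
  expect_equal(t1$DFC, 1 / 2)
  expect_equal(t1$DCC, 0)

  two <- igraph::make_graph(c("a", "b", "c", "d"), directed = FALSE)
  expect_error(node_importance(two), "disconnected")
})

test_that("all six metrics agree with brute-force oracles on random graphs", {
  for (s in 1:25) {
    n <- withr::with_seed(900 + s, sample(4:12, 1))
    adj <- random_connected_adj(n, seed = 900 + s)
    imp <- node_importance(adj_to_graph(adj))
    orc <- oracle_importance(adj)
    for (mt in c("DC", "CC", "BC", "DFC", "DCC", "DDC"))
      expect_equal(imp[[mt]], orc[[mt]], tolerance = 1e-10,
                   info = sprintf("metric %s seed %d", mt, s))
  }
})

test_that("cut vertices score strictly higher DFC than non-cut vertices", {
  for (s in 1:10) {
    adj <- random_connected_adj(withr::with_seed(1200 + s, sample(5:10, 1)),
                                seed = 1300 + s)
    imp <- node_importance(adj_to_graph(adj))
    cut <- vapply(seq_len(nrow(adj)), function(i)
      n_components(adj[-i, -i, drop = FALSE]) > 1, logical(1))
    if (any(cut) && any(!cut))
      expect_gt(min(imp$DFC[cut]), max(imp$DFC[!cut]))
    expect_true(all(imp$DFC >= 0 & imp$DFC <= 1))
    expect_true(all(imp$DCC >= 0 & imp$DCC <= 1))
    expect_true(all(imp$DDC >= 0 & imp$DDC <= 1))
  }
})

test_that("TF ranking uses competition ranks and shared final positions", {
  tab <- data.frame(node = c("a", "b", "c"),
                    DC = c(5, 5, 3), CC = c(0.5, 0.4, 0.3),
                    BC = c(2, 1, 0), DFC = c(1, 1, 1),
                    DCC = c(0.2, 0.1, 0.3), DDC = c(0.9, 0.8, 0.7))
  rk <- rank_transcription_factors(tab, c("a", "b", "c"))
  expect_equal(rk$rank_DC[rk$tf %in% c("a", "b")], c(1, 1)) # tie -> min rank
  expect_equal(rk$rank_DC[rk$tf == "c"], 3)
  expect_equal(rk$rank_DFC, c(1, 1, 1))
  # a TF ranked first everywhere lands at position 1
  expect_equal(rk$position[rk$tf == "a"], 1)
  # equal average ranks share a final position
  tab2 <- data.frame(node = c("a", "b"), DC = c(2, 1), CC = c(1, 2),
                     BC = c(2, 1), DFC = c(1, 2), DCC = c(2, 1), DDC = c(1, 2))
  rk2 <- rank_transcription_factors(tab2, c("a", "b"))
  expect_equal(rk2$average_rank, c(1.5, 1.5))
  expect_equal(rk2$position, c(1, 1))
})

test_that("metric diagnostics report tie widths and concordance with the consensus", {
  tab <- data.frame(node = letters[1:4],
                    DC = c(4, 3, 2, 1),       # fully resolved, equals consensus
                    CC = c(4, 3, 2, 1),
                    BC = c(4, 3, 2, 1),
                    DFC = c(1, 1, 1, 1),      # fully tied
                    DCC = c(2, 2, 1, 1),
                    DDC = c(4, 3, 2, 1))
  diag <- metric_diagnostics(tab, letters[1:4])
  expect_equal(diag$sensitivity[diag$metric == "DC"], 1)
  expect_equal(diag$sensitivity[diag$metric == "DFC"], 4)
  expect_equal(diag$sensitivity[diag$metric == "DCC"], 2)
  expect_equal(mean(diag$relative_power), 1, tolerance = 1e-12)
  expect_gte(diag$relative_power[diag$metric == "DC"],
             diag$relative_power[diag$metric == "DFC"])
})
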