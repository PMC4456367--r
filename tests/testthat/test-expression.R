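planted_matrix <- function(n = 30, k = 3, effect = 2, genes = 500,
                           markers = 100, seed = 5) {
  labels <- setNames(rep_len(seq_len(k), n), sprintf("S%02d", seq_len(n)))
  cfg <- sim_config(n_expr_probes = genes, n_expr_clusters = k,
                    markers_per_cluster = markers, log2_effect = effect)
  list(x = simulate_expression(labels, cfg, seed = seed),
       labels = labels)
}

test_that("global normalization sets every column mean to the target", {
  set.seed(1)
  x <- matrix(rexp(200, 1 / 80), 20, 10)
  xn <- global_normalize(x)
  expect_equal(unname(colMeans(xn)), rep(100, 10), tolerance = 1e-9)
  # idempotent and scale-invariant
  expect_equal(global_normalize(xn), xn)
  expect_equal(global_normalize(x * 10), xn)
  # constant column of 50 becomes constant 100
  xc <- matrix(50, 5, 2)
  expect_equal(unname(global_normalize(xc)[1, ]), c(100, 100))
  x0 <- x; x0[, 3] <- 0
  expect_error(global_normalize(x0), "all-zero")
})

test_that("probe filter applies max/mean/CV thresholds exactly", {
  # boundary probes: max 99 removed, constant removed
  x <- rbind(max99 = c(99, rep(5, 19)),
             passing = c(150, rep(40, 19)),
             constant = rep(120, 20),
             low_mean = c(150, rep(0, 19)))
  kept <- filter_probes(x)
  expect_identical(rownames(kept), "passing")
  # 1000-probe fixture vs brute-force per-probe re-evaluation
  set.seed(8)
  big <- matrix(rlnorm(1000 * 12, meanlog = 3, sdlog = 1.5), 1000, 12)
  rownames(big) <- sprintf("p%04d", 1:1000)
  cfg <- filter_config()
  keep_oracle <- apply(big, 1, function(v)
    max(v) >= cfg$max_signal && mean(v) >= cfg$mean_signal &&
      sd(v) / mean(v) >= cfg$cv)
  expect_identical(rownames(filter_probes(big, cfg)),
                   rownames(big)[keep_oracle])
  # monotone: raising any threshold never adds a probe
  tighter <- filter_probes(big, filter_config(max_signal = 200,
                                              mean_signal = 20, cv = 0.5))
  expect_true(all(rownames(tighter) %in% rownames(filter_probes(big, cfg))))
  expect_warning(filter_probes(big, filter_config(cv = 1e6)), "no probes")
})

test_that("hierarchical clustering recovers planted structure", {
  pm <- planted_matrix()
  hc <- hierarchical_clusters(pm$x, 3)
  expect_equal(ari(hc$labels, pm$labels), 1.0)
  # duplicate columns co-cluster at every k
  xd <- cbind(pm$x, dup = pm$x[, 1])
  for (k in 2:4) {
    l <- hierarchical_clusters(xd, k)$labels
    expect_equal(unname(l["dup"]), unname(l[1]))
  }
  expect_error(hierarchical_clusters(pm$x, 1), "at least 2")
  # two well-separated blobs split exactly at k = 2
  set.seed(3)
  blob <- cbind(matrix(rlnorm(300, 2, 0.1), 30, 10),
                matrix(rlnorm(300, 7, 0.1), 30, 10))
  colnames(blob) <- c(sprintf("a%d", 1:10), sprintf("b%d", 1:10))
  lb <- hierarchical_clusters(blob, 2)$labels
  expect_equal(length(unique(lb[1:10])), 1)
  expect_equal(length(unique(lb[11:20])), 1)
  expect_false(lb[1] == lb[11])
})

test_that("consensus matrices are valid co-clustering frequencies", {
  pm <- planted_matrix(n = 18, genes = 300, markers = 60)
  cons <- consensus_kmeans(pm$x, k_range = 2:3, n_iter = 50, seed = 1)
  for (cm in cons$consensus) {
    expect_true(isSymmetric(cm))
    expect_true(all(diag(cm) == 1))
    expect_true(all(cm >= 0 & cm <= 1))
  }
  # planted blocks: within-cluster consensus high, between low at k = 3
  cm <- cons$consensus[["3"]]
  same <- outer(pm$labels, pm$labels, "==")
  off_diag <- !diag(TRUE, nrow(cm))
  expect_gte(mean(cm[same & off_diag]), 0.9)
  expect_lte(mean(cm[!same]), 0.1)
  expect_gte(ari(cons$labels[["3"]], pm$labels), 0.9)
  expect_error(consensus_kmeans(pm$x, n_iter = 0), "n_iter")
})

test_that("two distinct samples never co-cluster at k = 2", {
  # exact co-clustering probability is 0: k-means on two points always
  # separates them, so the consensus off-diagonal must be exactly 0
  x <- cbind(A = c(10, 10, 200), B = c(200, 200, 10))
  cons <- consensus_kmeans(x, k_range = 2, n_iter = 25, seed = 2)
  expect_equal(cons$consensus[["2"]]["A", "B"], 0)
})

test_that("gene subsampling falls back to all genes when short", {
  pm <- planted_matrix(n = 12, genes = 80, markers = 20)
  cons <- consensus_kmeans(pm$x, k_range = 3, n_iter = 30,
                           n_genes = 10000, seed = 4)
  expect_equal(cons$n_genes, 80)
  expect_gte(ari(cons$labels[["3"]], pm$labels), 0.9)
})

test_that("NMF rank selection prefers the true block count", {
  # ideal block-diagonal consensus with 3 equal blocks
  blocks <- kronecker(diag(3), matrix(1, 6, 6))
  dimnames(blocks) <- list(sprintf("S%02d", 1:18), sprintf("S%02d", 1:18))
  res <- select_k_nmf(list("2" = blocks, "3" = blocks), k_range = 2:3,
                      n_restarts = 10, seed = 6)
  expect_lt(res$errors[["3"]], res$errors[["2"]])
  # rank-1 consensus (all ones): every rank fits; tie-break smallest k
  ones <- matrix(1, 10, 10)
  res1 <- select_k_nmf(list("2" = ones, "3" = ones, "4" = ones),
                       k_range = 2:4, n_restarts = 5, seed = 7)
  expect_true(all(res1$errors < 1e-3))
  expect_equal(res1$chosen_k, 2)
})

test_that("marker ranking puts planted markers on top and is antisymmetric", {
  pm <- planted_matrix(n = 20, k = 2, genes = 400, markers = 50)
  mk <- attr(pm$x, "markers")
  rk <- rank_marker_genes(pm$x, pm$labels, 1, 2)
  top <- rk$gene[seq_len(50)]
  expect_setequal(top, rownames(pm$x)[mk[[1]]])
  rev_rk <- rank_marker_genes(pm$x, pm$labels, 2, 1)
  expect_equal(sort(rev_rk$log2_ratio), sort(-rk$log2_ratio))
  # identical clusters give all-zero ratios
  same <- rank_marker_genes(cbind(pm$x, pm$x), rep(1:2, each = 20), 1, 2)
  expect_true(all(abs(same$log2_ratio) < 1e-12))
  expect_error(rank_marker_genes(pm$x, pm$labels, 1, 99), "non-empty")
})
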