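test_that("cluster_enrichment_sweep computes fractions and enrichment", {
  genes <- paste0("g", sprintf("%02d", 1:20))
  cl <- tibble::tibble(
    gene_id = genes,
    cluster = rep(1:3, times = c(5, 7, 8))
  )
  rhy <- c(genes[1:4], genes[6])   # 4 of 5 in cluster 1, 1 in cluster 2
  sw <- cluster_enrichment_sweep(cl, rhy, genes)
  expect_s3_class(sw, "cluster_sweep")
  per <- sw$clusters[order(sw$clusters$cluster), ]
  expect_equal(per$size, c(5, 7, 8))
  expect_equal(per$n_rhythmic, c(4, 1, 0))
  expect_equal(per$frac_rhythmic, c(4 / 5, 1 / 7, 0))
  # only cluster 1 is meaningful (>= 2 rhythmic members)
  expect_equal(per$meaningful, c(TRUE, FALSE, FALSE))
  # one meaningful cluster -> Bonferroni factor 1; hand value:
  # P(X >= 4), X ~ Hypergeom(5 rhythmic in 20, draw 5) = 76/15504
  expect_equal(per$p_raw[1], 76 / 15504, tolerance = 1e-12)
  expect_equal(per$p_adjusted[1], per$p_raw[1])
  expect_true(per$significant[1])
  # at K <= 80 the significant cluster is pooled: precision 4/5, recall 4/5
  r50 <- sw$curve[sw$curve$k_pct == 50, ]
  expect_equal(r50$n_predicted, 5)
  expect_equal(r50$precision, 4 / 5)
  expect_equal(r50$recall, 4 / 5)
  # at K = 85 the fraction rule excludes it
  expect_equal(sw$curve$n_predicted[sw$curve$k_pct == 85], 0)
})

test_that("randomized null preserves cluster sizes and is deterministic", {
  cl <- tibble::tibble(gene_id = paste0("g", 1:12),
                       cluster = rep(1:3, times = c(6, 4, 2)))
  sw <- cluster_enrichment_sweep(cl, paste0("g", 1:5), cl$gene_id)
  n1 <- randomized_cluster_null(sw, n_rand = 10, seed = 42)
  n2 <- randomized_cluster_null(sw, n_rand = 10, seed = 42)
  expect_identical(n1, n2)
  expect_equal(dim(n1), c(10, 100))
  expect_true(all(is.finite(n1)))
})

test_that("predict_from_clusters gates on the null 95th percentile", {
  cl <- tibble::tibble(gene_id = paste0("g", 1:30),
                       cluster = rep(1:3, each = 10))
  # cluster 1 almost purely rhythmic: strong signal
  rhy <- c(paste0("g", 1:9), "g15")
  sw <- cluster_enrichment_sweep(cl, rhy, cl$gene_id)
  null_f <- randomized_cluster_null(sw, n_rand = 100, seed = 1)
  pred <- predict_from_clusters(sw, null_f)
  expect_true(pred$gate_passed)
  expect_equal(pred$novel, "g10")
  expect_setequal(pred$predicted, paste0("g", 1:10))
  # an all-zero real curve never passes
  sw0 <- cluster_enrichment_sweep(cl, c("g1", "g11", "g21", "g25"), cl$gene_id)
  pred0 <- predict_from_clusters(sw0, randomized_cluster_null(sw0, 20, 1))
  if (!pred0$gate_passed) {
    expect_equal(pred0$predicted, character())
    expect_true(is.na(pred0$chosen_k))
  }
})

test_that("predict_rhythmic_clusters recovers module members end to end", {
  sim <- simulate_expression(sim_config(n_genes = 120, frac_rhythmic = 0.3,
                                        n_modules = 3, seed = 4))
  coll <- collapse_replicates(sim$expression)
  nets <- build_standard_networks(coll)
  lcc <- dielnet::largest_component(nets$SIGN_N)
  nodes <- igraph::V(lcc$graph)$name
  truth <- sim$truth
  rhy_all <- truth$gene_id[truth$is_rhythmic]
  rhy <- intersect(rhy_all, nodes)
  res <- predict_rhythmic_clusters(list(SIGN_N = lcc), rhy, n_rand = 50,
                                   seed = 9)
  expect_s3_class(res, "cluster_prediction")
  expect_named(res$per_network, "SIGN_N")
  expect_true(all(res$novel %in% setdiff(nodes, rhy)))
  expect_equal(res$novel, res$predictions$gene_id)
  # determinism
  res2 <- predict_rhythmic_clusters(list(SIGN_N = lcc), rhy, n_rand = 50,
                                    seed = 9)
  expect_identical(res$predictions, res2$predictions)
})
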