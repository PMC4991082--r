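test_that("separation_test matches wilcox.test and reports direction", {
  a <- c(5, 6, 7, 8, 9)
  b <- c(1, 2, 3, 4, 5)
  st <- separation_test(a, b)
  expect_equal(st$p_value,
               suppressWarnings(wilcox.test(a, b)$p.value))
  expect_equal(st$direction, "most_central")
  expect_equal(separation_test(b, a)$direction, "least_central")
  expect_error(separation_test(numeric(), b), "non-empty")
})

test_that("sweep_centrality computes exact precision/recall at each K", {
  cent <- setNames(c(10, 9, 8, 2, 1), paste0("g", 1:5))
  rhy <- c("g1", "g2", "g4")
  sw <- sweep_centrality(cent, rhy, "most_central")
  expect_equal(sw$ranked, paste0("g", 1:5))
  # K = 40% -> top 2 = g1, g2: precision 1, recall 2/3
  r40 <- sw$curve[sw$curve$k_pct == 40, ]
  expect_equal(r40$n_top, 2)
  expect_equal(r40$precision, 1)
  expect_equal(r40$recall, 2 / 3)
  # K = 100% -> precision 3/5, recall 1
  r100 <- sw$curve[sw$curve$k_pct == 100, ]
  expect_equal(r100$precision, 3 / 5)
  expect_equal(r100$recall, 1)
  # best K is the smallest argmax of F
  expect_equal(sw$best_k, which.max(sw$curve$f_score))
  # ties in centrality are broken by gene id
  cent2 <- setNames(rep(1, 3), c("b", "a", "c"))
  expect_equal(sweep_centrality(cent2, "a")$ranked, c("a", "b", "c"))
  expect_error(sweep_centrality(cent, c("g1", "zz")), "subset")
})

test_that("enrichment_gate applies the Bonferroni factor and cap", {
  g <- enrichment_gate(paste0("g", 1:5), paste0("g", 1:5),
                       paste0("g", 1:20), n_tests = 35)
  expect_equal(g$overlap, 5)
  expect_equal(g$p_raw, 1 / choose(20, 5))
  expect_equal(g$p_adjusted, min(1, 35 / choose(20, 5)))
  expect_true(g$pass)
  weak <- enrichment_gate("g1", c("g1", "g2"), paste0("g", 1:4), n_tests = 35)
  expect_equal(weak$p_adjusted, 1)
  expect_false(weak$pass)
  expect_error(enrichment_gate("zz", "g1", paste0("g", 1:4)), "universe")
})

test_that("centrality prediction finds planted hubs and reports structure", {
  # a clique of rhythmic genes plus higher-degree novel members, against a
  # sparse periphery chain
  core <- paste0("core", sprintf("%02d", 1:12))
  per <- paste0("per", sprintf("%02d", 1:30))
  edges <- t(combn(core, 2))
  chain <- cbind(c(core[1], per[-length(per)]), per)
  # boost the 3 scan-missed core genes above the rest of the clique so the
  # F-optimal band has to include them
  extra <- cbind(rep(core[10:12], each = 4), rep(per[1:4], 3))
  g <- igraph::graph_from_edgelist(rbind(edges, chain, extra),
                                   directed = FALSE)
  net <- as_fixture_network(g)
  rhythmic <- core[1:9]          # 3 core genes are "missed" by the scan
  res <- predict_rhythmic_centrality(list(NET = net), rhythmic,
                                     measures = "degree")
  expect_s3_class(res, "centrality_prediction")
  expect_equal(nrow(res$combinations), 1)
  expect_true(all(res$combinations$pass))
  expect_equal(res$combinations$direction, "most_central")
  expect_true(all(core[10:12] %in% res$novel))
  expect_false(any(per[5:30] %in% res$novel))
  expect_true(all(res$predictions$support == 1))
  expect_true(all(grepl("NET:degree", res$predictions$combinations)))
})

test_that("no combination passes when rhythmic genes are placed at random", {
  g <- igraph::make_lattice(c(6, 6))
  net <- as_fixture_network(g)
  nodes <- igraph::V(net$graph)$name
  withr::with_seed(7, rhy <- sample(nodes, 10))
  res <- predict_rhythmic_centrality(list(L = net), rhy,
                                     measures = c("degree", "closeness"))
  expect_equal(length(res$novel), 0)
  expect_equal(nrow(res$predictions), 0)
})

test_that("precomputed centralities give identical results", {
  net <- as_fixture_network(igraph::make_star(8, mode = "undirected"))
  cents <- list(S = node_centrality(net))
  rhy <- igraph::V(net$graph)$name[1:3]
  a <- predict_rhythmic_centrality(list(S = net), rhy)
  b <- predict_rhythmic_centrality(list(S = net), rhy, centralities = cents)
  expect_equal(a$combinations, b$combinations)
  expect_equal(a$novel, b$novel)
})
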