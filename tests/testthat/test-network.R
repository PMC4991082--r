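make_profiles <- function(m) {
  # rows = genes, cols = timepoints; wraps into a collapsed-style tibble
  labs <- sub("_r[0-9]+$", "",
              dielnet:::format_zt_label(seq(0, by = 4,
                                            length.out = ncol(m)), 1L))
  colnames(m) <- labs
  out <- tibble::tibble(gene_id = rownames(m)) %>%
    dplyr::bind_cols(tibble::as_tibble(m))
  attr(out, "zt") <- seq(0, by = 4, length.out = ncol(m))
  out
}

test_that("pearson scores match cor() and abs variant", {
  withr::with_seed(1, m <- matrix(rnorm(5 * 12), 5,
                                  dimnames = list(paste0("g", 1:5), NULL)))
  x <- make_profiles(m)
  sc <- coexpression_scores(x, "signed_pearson")
  expect_equal(sc$score["g1", "g2"], cor(m[1, ], m[2, ]))
  sa <- coexpression_scores(x, "abs_pearson")
  expect_equal(sa$score["g1", "g2"], abs(cor(m[1, ], m[2, ])))
  expect_true(is.na(sc$score["g1", "g1"]))
})

test_that("zero-variance genes are excluded from Pearson with a warning", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = rep(5, 4), g3 = c(4, 3, 2, 1))
  x <- make_profiles(m)
  expect_warning(sc <- coexpression_scores(x, "signed_pearson"),
                 "zero-variance")
  expect_setequal(sc$genes, c("g1", "g3"))
})

test_that("mutual information matches a hand computation", {
  # x,y in {lo,hi} perfectly dependent over 4 points, 2 bins -> 1 bit
  expect_equal(mutual_information(c(0, 0, 9, 9), c(1, 1, 8, 8), bins = 2), 1)
  # independent 2x2 table -> 0 bits
  expect_equal(mutual_information(c(0, 0, 9, 9), c(1, 8, 1, 8), bins = 2), 0)
  # 3-bin identity -> log2(3)
  expect_equal(mutual_information(rep(c(1, 5, 9), 2), rep(c(1, 5, 9), 2),
                                  bins = 3), log2(3))
  # symmetric
  withr::with_seed(2, { a <- rnorm(12); b <- rnorm(12) })
  expect_equal(mutual_information(a, b), mutual_information(b, a))
})

test_that("equal-width binning is by value range, not quantile", {
  b <- dielnet:::bin_profiles(rbind(g = c(0, 1, 2, 10)), 2)
  # width 10: values 0,1,2 in bin 1; 10 in bin 2
  expect_equal(as.integer(b), c(1, 1, 1, 2))
})

test_that("top-K selection keeps exactly K edges with tie-break", {
  s <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  s["a", "b"] <- s["b", "a"] <- 0.9
  s["a", "c"] <- s["c", "a"] <- 0.5
  s["a", "d"] <- s["d", "a"] <- 0.5
  s["b", "c"] <- s["c", "b"] <- 0.5
  s["b", "d"] <- s["d", "b"] <- 0.1
  s["c", "d"] <- s["d", "c"] <- 0.2
  diag(s) <- NA
  sc <- structure(list(score = s, method = "signed_pearson",
                       genes = letters[1:4]), class = "coexpr_scores")
  net <- build_network(sc, k_multiplier = 0.75)   # K = 3 of 6 pairs
  e <- tidy(net)
  expect_equal(nrow(e), 3)
  expect_equal(e$gene_a, c("a", "a", "a"))
  expect_equal(e$gene_b, c("b", "c", "d"))        # ties at 0.5: a-c, a-d beat b-c
  # K larger than the pair count warns and builds the complete graph
  expect_warning(full <- build_network(sc, 10), "complete graph")
  expect_equal(igraph::ecount(full$graph), 6)
})

test_that("intersection keeps common edges and drops isolated nodes", {
  s1 <- tibble::tribble(~from, ~to, "a", "b", "b", "c", "c", "d")
  s2 <- tibble::tribble(~from, ~to, "a", "b", "c", "d", "a", "d")
  g1 <- igraph::graph_from_data_frame(s1, FALSE, vertices = letters[1:4])
  g2 <- igraph::graph_from_data_frame(s2, FALSE, vertices = letters[1:4])
  n1 <- dielnet:::new_coexpr_network(g1, "X", 1, letters[1:4])
  n2 <- dielnet:::new_coexpr_network(g2, "Y", 1, letters[1:4])
  iv <- intersect_networks(n1, n2)
  e <- tidy(iv)
  expect_equal(paste(e$gene_a, e$gene_b), c("a b", "c d"))
  expect_setequal(igraph::V(iv$graph)$name, c("a", "b", "c", "d"))
  n3 <- dielnet:::new_coexpr_network(g2, "Z", 1, letters[1:5])
  expect_error(intersect_networks(n1, n3), "universe")
})

test_that("largest_component picks the biggest, ties by smallest node", {
  ed <- tibble::tribble(~from, ~to, "x", "y", "b", "c", "a", "c")
  g <- igraph::graph_from_data_frame(ed, FALSE)
  net <- dielnet:::new_coexpr_network(g, "T", 1, igraph::V(g)$name)
  lcc <- dielnet::largest_component(net)
  expect_setequal(igraph::V(lcc$graph)$name, c("a", "b", "c"))
  # equal sizes: component containing "a" wins
  ed2 <- tibble::tribble(~from, ~to, "x", "y", "a", "b")
  g2 <- igraph::graph_from_data_frame(ed2, FALSE)
  net2 <- dielnet:::new_coexpr_network(g2, "T", 1, igraph::V(g2)$name)
  lcc2 <- dielnet::largest_component(net2)
  expect_setequal(igraph::V(lcc2$graph)$name, c("a", "b"))
})

test_that("standard panel has the advertised structure", {
  sim <- simulate_expression(sim_config(n_genes = 60, frac_rhythmic = 0.2,
                                        n_modules = 2, seed = 5))
  coll <- collapse_replicates(sim$expression)
  nets <- build_standard_networks(coll)
  expect_named(nets, c("SIGN_N", "ABS_N", "MI_N", "ABS_MI_10N", "ABS_MI_25N"))
  n <- nrow(coll)
  expect_equal(igraph::ecount(nets$SIGN_N$graph), n)
  expect_equal(igraph::ecount(nets$ABS_N$graph), n)
  expect_equal(igraph::ecount(nets$MI_N$graph), n)
  # intersections are subsets of both parents' budgets
  expect_lte(igraph::ecount(nets$ABS_MI_10N$graph), 10 * n)
  expect_lte(igraph::ecount(nets$ABS_MI_25N$graph), 25 * n)
  # 10N intersection edges are all present in the 25N intersection
  e10 <- tidy(nets$ABS_MI_10N); e25 <- tidy(nets$ABS_MI_25N)
  expect_true(all(paste(e10$gene_a, e10$gene_b) %in%
                    paste(e25$gene_a, e25$gene_b)))
  ov <- network_edge_overlap(nets)
  expect_equal(nrow(ov), 10)
  expect_true(all(ov$jaccard >= 0 & ov$jaccard <= 1))
})

test_that("standard panel shares one universe when a gene has zero variance", {
  ids <- sprintf("g%02d", 1:60)
  withr::with_seed(4, m <- matrix(rnorm(60 * 12), 60,
                                  dimnames = list(ids, NULL)))
  m[3, ] <- 5   # constant gene: excluded from Pearson scoring
  x <- make_profiles(m)
  expect_warning(nets <- build_standard_networks(x), "zero-variance")
  for (net in nets) {
    expect_setequal(net$universe, ids[-3])
  }
})

test_that("glance reports consistent counts", {
  net <- two_triangle_network()
  gl <- glance(net)
  expect_equal(gl$n_nodes, 6)
  expect_equal(gl$n_edges, 7)
  expect_equal(gl$n_components, 1)
  expect_equal(gl$lcc_nodes, 6)
})
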