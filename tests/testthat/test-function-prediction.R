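make_ann <- function(...) {
  pairs <- list(...)
  tibble::tibble(gene = purrr::map_chr(pairs, 1),
                 term = purrr::map_chr(pairs, 2))
}

test_that("group_term_enrichment matches hand hypergeometric values", {
  universe <- paste0("g", 1:20)
  ann <- tibble::tibble(gene = paste0("g", 1:8),
                        term = rep(c("T1", "T2"), each = 4))
  # group of 5 contains all 4 T1 genes and one T2 gene
  grp <- c("g1", "g2", "g3", "g4", "g5")
  enr <- group_term_enrichment(grp, ann, universe)
  t1 <- enr[enr$term == "T1", ]
  expect_equal(t1$n_group, 4)
  expect_equal(t1$n_universe, 4)
  expect_equal(t1$p_raw, dielnet:::hyper_upper_p(4, 5, 4, 20))
  # two terms tested -> Bonferroni factor 2
  expect_equal(t1$p_adjusted, min(1, 2 * t1$p_raw))
  expect_true(t1$significant)
  t2 <- enr[enr$term == "T2", ]
  expect_false(t2$significant)
  expect_error(group_term_enrichment(character(), ann, universe), "empty")
  expect_error(group_term_enrichment("zz", ann, universe), "universe")
})

test_that("prediction_groups assembles bands and clusters with universes", {
  cent <- structure(list(bands = list(
    "N:degree" = list(genes = c("a", "b"), universe = letters[1:5],
                      network = "N", measure = "degree")
  )), class = "centrality_prediction")
  clus <- structure(list(clusters = list(
    M = list(clusters = list(`1` = c("c", "d"), `2` = c("a", "e")),
             universe = letters[1:5])
  )), class = "cluster_prediction")
  g <- prediction_groups(cent, clus)
  expect_named(g, c("centrality", "clustering"))
  expect_equal(g$centrality[["N:degree"]]$genes, c("a", "b"))
  expect_equal(length(g$clustering), 2)
  expect_equal(g$clustering[["M:1"]]$genes, c("c", "d"))
  expect_equal(g$clustering[["M:2"]]$universe, letters[1:5])
})

test_that("predict_annotations propagates enriched terms to lacking members", {
  universe <- paste0("g", sprintf("%02d", 1:30))
  # term T annotates g01..g05; group holds those plus unannotated g06
  ann <- tibble::tibble(gene = paste0("g0", 1:5), term = "T")
  grp <- list(genes = c(paste0("g0", 1:5), "g06"), universe = universe)
  groups <- list(centrality = list(b1 = grp), clustering = list(c1 = grp))
  out <- predict_annotations(groups, ann)
  expect_s3_class(out, "function_prediction")
  expect_equal(out$gene, "g06")
  expect_equal(out$term, "T")
  expect_equal(out$source, "both")
  expect_equal(out$gene_status, "uncharacterized")
  # a gene annotated with another term is "characterized"
  ann2 <- dplyr::bind_rows(ann, tibble::tibble(gene = "g06", term = "OTHER"))
  out2 <- predict_annotations(groups, ann2)
  expect_equal(out2$gene_status[out2$gene == "g06"], "characterized")
  # empty groups give a typed empty result
  empty <- predict_annotations(list(centrality = list(), clustering = list()),
                               ann)
  expect_equal(nrow(empty), 0)
  expect_s3_class(empty, "function_prediction")
})

test_that("LOOCV scores hidden annotations correctly", {
  universe <- paste0("g", sprintf("%02d", 1:40))
  # a coherent group: 6 genes all annotated T
  ann <- tibble::tibble(gene = paste0("g0", 1:6), term = "T")
  grp <- list(genes = paste0("g0", 1:6), universe = universe)
  groups <- list(centrality = list(b = grp), clustering = list(c = grp))
  res <- loocv_precision(groups, ann)
  expect_equal(res$n_genes_evaluated, 6)
  # hiding any member still leaves 5/6 annotated -> T recovered every time
  expect_equal(res$n_predicted_pairs, 6)
  expect_equal(res$n_correct_pairs, 6)
  expect_equal(res$precision, 1)
})

test_that("LOOCV precision degrades with incoherent annotations", {
  universe <- paste0("g", sprintf("%02d", 1:40))
  grp <- list(genes = paste0("g0", 1:6), universe = universe)
  groups <- list(centrality = list(b = grp), clustering = list(c = grp))
  # 5 genes share term T, the 6th carries an unrelated singleton term
  ann <- dplyr::bind_rows(
    tibble::tibble(gene = paste0("g0", 1:5), term = "T"),
    tibble::tibble(gene = "g06", term = "X"))
  res <- loocv_precision(groups, ann)
  # when g06 is held out, T is predicted for it but its truth is X
  expect_lt(res$precision, 1)
  expect_gt(res$n_predicted_pairs, res$n_correct_pairs)
})
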