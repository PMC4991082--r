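#' Cluster enrichment sweep
#'
#' For an MCL clustering of one network, restricts attention to meaningful
#' clusters (size >= 2 with >= 2 rhythmic members), computes each cluster's
#' rhythmic fraction and Bonferroni-adjusted hypergeometric enrichment p
#' (Bonferroni factor = number of meaningful clusters), and then, for each K
#' from 1 to 100 percent, pools the genes of clusters that pass both the
#' fraction rule (rhythmic fraction >= K%) and the enrichment gate
#' (adjusted p < `alpha`), scoring the pooled predictions against the
#' rhythmic set by precision, recall and F.
#'
#' @param clustering `mcl_clustering` tibble (or any `gene_id`/`cluster`
#'   tibble partitioning the universe).
#' @param rhythmic Rhythmic gene ids within this network.
#' @param universe All gene ids of the analysed network.
#' @param alpha Enrichment significance level after Bonferroni (default 0.05).
#' @return A list of class `cluster_sweep`: `clusters` (per-cluster table),
#'   `curve` (per-K tibble with `k_pct`, `n_predicted`, `precision`,
#'   `recall`, `f_score`) and the inputs needed downstream.
#' @export
cluster_enrichment_sweep <- function(clustering, rhythmic, universe,
                                     alpha = 0.05) {
  cl <- clustering[clustering$gene_id %in% universe, ]
  rhythmic <- intersect(rhythmic, universe)
  per <- cl %>%
    group_by(.data$cluster) %>%
    summarise(size = dplyr::n(),
              n_rhythmic = sum(.data$gene_id %in% rhythmic),
              .groups = "drop") %>%
    mutate(frac_rhythmic = .data$n_rhythmic / .data$size,
           meaningful = .data$size >= 2 & .data$n_rhythmic >= 2)
  n_meaningful <- sum(per$meaningful)
  per$p_raw <- NA_real_
  per$p_adjusted <- NA_real_
  if (n_meaningful > 0) {
    idx <- which(per$meaningful)
    per$p_raw[idx] <- vapply(idx, function(i) {
      hyper_upper_p(per$n_rhythmic[i], per$size[i], length(rhythmic),
                    length(universe))
    }, 1)
    per$p_adjusted[idx] <- pmin(1, per$p_raw[idx] * n_meaningful)
  }
  per$significant <- per$meaningful & !is.na(per$p_adjusted) &
    per$p_adjusted < alpha

  genes_by_cluster <- split(cl$gene_id, cl$cluster)
  curve <- purrr::map(1:100, function(k) {
    pass <- per$cluster[per$significant & per$frac_rhythmic >= k / 100]
    genes <- unlist(genes_by_cluster[as.character(pass)], use.names = FALSE)
    tp <- length(intersect(genes, rhythmic))
    np <- length(genes)
    precision <- if (np > 0) tp / np else 0
    recall <- if (length(rhythmic) > 0) tp / length(rhythmic) else 0
    f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    tibble(k_pct = k, n_clusters = length(pass), n_predicted = np,
           precision = precision, recall = recall, f_score = f)
  }) %>% bind_rows()

  structure(list(clusters = per, curve = curve,
                 genes_by_cluster = genes_by_cluster,
                 rhythmic = rhythmic, universe = universe, alpha = alpha),
            class = "cluster_sweep")
}

#' Randomized-clustering null for the cluster sweep
#'
#' Reclusters the network at random `n_rand` times, preserving the real
#' cluster-size multiset exactly (genes are shuffled among clusters), and
#' recomputes the full enrichment sweep for each replicate.
#'
#' @param sweep A `cluster_sweep` from [cluster_enrichment_sweep()].
#' @param n_rand Number of random clusterings (default 100).
#' @param seed Integer seed; the null is deterministic given it.
#' @return Matrix of null F-scores, `n_rand` rows by 100 K columns.
#' @export
randomized_cluster_null <- function(sweep, n_rand = 100, seed = 1L) {
  sizes <- vapply(sweep$genes_by_cluster, length, 1L)
  genes <- unlist(sweep$genes_by_cluster, use.names = FALSE)
  withr::with_seed(as.integer(seed), {
    out <- matrix(NA_real_, n_rand, 100)
    for (r in seq_len(n_rand)) {
      shuffled <- sample(genes)
      cl <- tibble(gene_id = shuffled,
                   cluster = rep(seq_along(sizes), times = sizes))
      sw <- cluster_enrichment_sweep(cl, sweep$rhythmic, sweep$universe,
                                     sweep$alpha)
      out[r, ] <- sw$curve$f_score
    }
    out
  })
}

#' Predict rhythmic genes from MCL clusters
#'
#' Picks the K at which the real sweep's F-score peaks (smallest K on ties)
#' and keeps the network's predictions only if that F-score exceeds the 95th
#' percentile of the randomized null F-scores at the same K; predictions are
#' the pooled genes of all significant clusters at the chosen K.
#'
#' @param sweep A `cluster_sweep`.
#' @param null_f Null F-score matrix from [randomized_cluster_null()].
#' @return A list: `chosen_k` (NA if the gate fails), `null_f95`, `predicted`
#'   (gene ids, empty if gated out), `novel` (predicted genes outside the
#'   rhythmic set) and `gate_passed`.
#' @export
predict_from_clusters <- function(sweep, null_f) {
  f <- sweep$curve$f_score
  k_star <- which.max(f)                     # smallest argmax by convention
  null_at_k <- sort(null_f[, k_star])
  f95 <- null_at_k[ceiling(0.95 * length(null_at_k))]
  passed <- f[k_star] > f95
  if (!passed || f[k_star] == 0) {
    return(list(chosen_k = NA_integer_, null_f95 = f95, predicted = character(),
                novel = character(), gate_passed = FALSE))
  }
  pass <- sweep$clusters$cluster[sweep$clusters$significant &
                                   sweep$clusters$frac_rhythmic >= k_star / 100]
  genes <- sort(unlist(sweep$genes_by_cluster[as.character(pass)],
                       use.names = FALSE))
  list(chosen_k = k_star, null_f95 = f95, predicted = genes,
       novel = setdiff(genes, sweep$rhythmic), gate_passed = TRUE)
}

#' Cluster-based rhythmic-gene prediction across networks
#'
#' Runs [mcl_cluster()], [cluster_enrichment_sweep()],
#' [randomized_cluster_null()] and [predict_from_clusters()] for each network
#' and aggregates the novel predictions with per-gene support counts (number
#' of contributing networks).
#'
#' @param networks Named list of connected `coexpr_network` objects.
#' @param rhythmic Rhythmic gene ids.
#' @param inflation MCL inflation (default 2).
#' @param n_rand Null replicates per network (default 100).
#' @param seed Integer seed.
#' @param alpha Cluster enrichment level (default 0.05).
#' @return A list of class `cluster_prediction`: `per_network` (list of
#'   sweep/null/prediction results), `predictions` (tibble `gene_id`,
#'   `support`, `networks`), `novel`, and `clusters` (list of significant
#'   cluster gene sets per contributing network, for function prediction).
#' @export
predict_rhythmic_clusters <- function(networks, rhythmic, inflation = 2,
                                      n_rand = 100, seed = 1L, alpha = 0.05) {
  per_network <- list()
  support <- list()
  sig_clusters <- list()
  clusterings <- list()
  for (i in seq_along(networks)) {
    tag <- names(networks)[i]
    net <- networks[[i]]
    nodes <- igraph::V(net$graph)$name
    cl <- mcl_cluster(net, inflation = inflation)
    sweep <- cluster_enrichment_sweep(cl, intersect(rhythmic, nodes), nodes,
                                      alpha)
    null_f <- randomized_cluster_null(sweep, n_rand, seed + i)
    pred <- predict_from_clusters(sweep, null_f)
    per_network[[tag]] <- list(clustering = cl, sweep = sweep,
                               null_f = null_f, prediction = pred)
    clusterings[[tag]] <- cl
    if (pred$gate_passed) {
      support[[tag]] <- pred$novel
      pass <- sweep$clusters$cluster[sweep$clusters$significant &
                                       sweep$clusters$frac_rhythmic >= pred$chosen_k / 100]
      sig_clusters[[tag]] <- list(
        clusters = sweep$genes_by_cluster[as.character(pass)],
        universe = nodes
      )
    }
  }
  pred_tbl <- if (length(support) > 0) {
    tibble(gene_id = unlist(support, use.names = FALSE),
           network = rep(names(support), lengths(support))) %>%
      group_by(.data$gene_id) %>%
      summarise(support = dplyr::n(),
                networks = paste(sort(.data$network), collapse = ";"),
                .groups = "drop") %>%
      arrange(desc(.data$support), .data$gene_id)
  } else {
    tibble(gene_id = character(), support = integer(), networks = character())
  }
  structure(list(per_network = per_network, predictions = pred_tbl,
                 novel = pred_tbl$gene_id, clusters = sig_clusters,
                 clusterings = clusterings),
            class = "cluster_prediction")
}
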