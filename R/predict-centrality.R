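#' Rank-based separation test between rhythmic and other genes
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of whether rhythmic genes
#' occupy different network positions than the remaining genes, plus the
#' direction of the difference.
#'
#' @param values_rhythmic,values_other Centrality values of the two groups
#'   (both non-empty).
#' @return A list with `p_value` and `direction`
#'   (`"most_central"` if rhythmic genes sit higher, else `"least_central"`).
#' @export
separation_test <- function(values_rhythmic, values_other) {
  if (length(values_rhythmic) == 0 || length(values_other) == 0) {
    abort("both groups must be non-empty")
  }
  p <- suppressWarnings(
    wilcox.test(values_rhythmic, values_other, alternative = "two.sided")$p.value
  )
  if (is.na(p)) p <- 1    # degenerate case: all values identical
  md <- median(values_rhythmic) - median(values_other)
  if (md == 0) md <- mean(values_rhythmic) - mean(values_other)
  list(p_value = p,
       direction = if (md >= 0) "most_central" else "least_central")
}

#' Precision/recall/F sweep over centrality thresholds
#'
#' Ranks genes by centrality in the stated direction and, for each `K` from 1
#' to 100 percent, evaluates the top `ceiling(K/100 * n)` genes against the
#' rhythmic set: precision (fraction of the top set that is rhythmic), recall
#' (fraction of rhythmic genes captured) and F-score. Ranking ties are broken
#' by gene id for determinism.
#'
#' @param centrality Named numeric vector (names = gene ids).
#' @param rhythmic Character vector of rhythmic gene ids (subset of names).
#' @param direction `"most_central"` (rank descending) or `"least_central"`.
#' @return A list with `curve` (tibble `k_pct`, `n_top`, `precision`,
#'   `recall`, `f_score`), `best_k` (smallest argmax-F K) and `ranked`
#'   (the deterministic gene ranking).
#' @export
sweep_centrality <- function(centrality, rhythmic,
                             direction = c("most_central", "least_central")) {
  direction <- match.arg(direction)
  if (length(rhythmic) == 0) abort("empty rhythmic set")
  if (!all(rhythmic %in% names(centrality))) {
    abort("rhythmic set must be a subset of the scored genes")
  }
  n <- length(centrality)
  ord <- if (direction == "most_central") {
    order(-centrality, names(centrality))
  } else {
    order(centrality, names(centrality))
  }
  ranked <- names(centrality)[ord]
  is_rhy <- ranked %in% rhythmic
  cum_tp <- cumsum(is_rhy)
  k_pct <- 1:100
  n_top <- ceiling(k_pct / 100 * n)
  tp <- cum_tp[n_top]
  precision <- tp / n_top
  recall <- tp / length(rhythmic)
  f <- ifelse(precision + recall > 0,
              2 * precision * recall / (precision + recall), 0)
  curve <- tibble(k_pct = k_pct, n_top = n_top, precision = precision,
                  recall = recall, f_score = f)
  list(curve = curve, best_k = k_pct[which.max(f)], ranked = ranked)
}

#' Hypergeometric enrichment gate with Bonferroni correction
#'
#' Upper-tail hypergeometric p-value of the overlap between a candidate gene
#' set and the rhythmic set, Bonferroni-multiplied by the number of
#' network-by-measure cases screened and capped at 1; passes if the adjusted
#' p is below `alpha`.
#'
#' @param top_set,rhythmic Gene-id vectors (subsets of `universe`).
#' @param universe Gene universe for the test.
#' @param n_tests Bonferroni factor (default 35 = 5 networks x 7 measures).
#' @param alpha Significance level (default 0.05).
#' @return List with `p_raw`, `p_adjusted`, `overlap`, `pass`.
#' @export
enrichment_gate <- function(top_set, rhythmic, universe, n_tests = 35,
                            alpha = 0.05) {
  if (!all(top_set %in% universe) || !all(rhythmic %in% universe)) {
    abort("sets must be subsets of the universe")
  }
  ov <- length(intersect(top_set, rhythmic))
  p <- hyper_upper_p(ov, length(top_set), length(rhythmic), length(universe))
  p_adj <- min(1, p * n_tests)
  list(p_raw = p, p_adjusted = p_adj, overlap = ov, pass = p_adj < alpha)
}

#' Predict rhythmic genes from network centrality profiles
#'
#' The full screen over network-by-centrality combinations: for each network
#' (analysed as its largest connected component) and each measure, (1) test
#' whether rhythmic genes occupy significantly different network positions
#' (two-sided Mann-Whitney, `alpha_separation`); (2) for significant cases,
#' sweep the top-K-percent band in the indicated direction and find the
#' F-score-optimal K; (3) gate that band on Bonferroni-corrected
#' hypergeometric enrichment in the rhythmic set. Genes in passing bands that
#' are not already in the rhythmic set become novel predictions, each
#' supported by the number of passing combinations containing it.
#'
#' @param networks Named list of connected `coexpr_network` objects (largest
#'   components).
#' @param rhythmic Character vector of scan-identified rhythmic gene ids.
#' @param measures Centrality measures to screen.
#' @param alpha_separation Mann-Whitney significance level (default 0.01).
#' @param alpha_enrichment Enrichment gate level (default 0.05).
#' @param centralities Optional pre-computed named list of centrality tables
#'   (as from [node_centrality()]), one per network.
#' @return A list of class `centrality_prediction`: `combinations` (one row
#'   per network-by-measure case with test results), `predictions`
#'   (tibble `gene_id`, `support`, `combinations`), `novel` (novel gene ids)
#'   and `bands` (list of passing top-K bands, for downstream function
#'   prediction).
#' @export
predict_rhythmic_centrality <- function(networks, rhythmic,
                                        measures = CENTRALITY_MEASURES,
                                        alpha_separation = 0.01,
                                        alpha_enrichment = 0.05,
                                        centralities = NULL) {
  if (is.null(centralities)) {
    centralities <- purrr::map(networks, node_centrality, measures = measures)
  }
  n_tests <- length(networks) * length(measures)
  combos <- list()
  bands <- list()
  support <- list()

  for (net_tag in names(networks)) {
    ct <- centralities[[net_tag]]
    nodes <- ct$gene_id
    rhy_here <- intersect(rhythmic, nodes)
    for (meas in measures) {
      vals <- setNames(ct[[meas]], nodes)
      row <- tibble(network = net_tag, measure = meas,
                    n_nodes = length(nodes), n_rhythmic = length(rhy_here),
                    separation_p = NA_real_, direction = NA_character_,
                    optimal_k_pct = NA_integer_, precision = NA_real_,
                    recall = NA_real_, f_score = NA_real_,
                    enrichment_p = NA_real_, pass = FALSE,
                    n_predicted = 0L, n_novel = 0L)
      if (length(rhy_here) > 0 && length(rhy_here) < length(nodes)) {
        sep <- separation_test(vals[rhy_here], vals[setdiff(nodes, rhy_here)])
        row$separation_p <- sep$p_value
        row$direction <- sep$direction
        if (sep$p_value < alpha_separation) {
          sw <- sweep_centrality(vals, rhy_here, sep$direction)
          best <- sw$curve[sw$curve$k_pct == sw$best_k, ]
          top_set <- sw$ranked[seq_len(best$n_top)]
          gate <- enrichment_gate(top_set, rhy_here, nodes, n_tests,
                                  alpha_enrichment)
          row$optimal_k_pct <- sw$best_k
          row$precision <- best$precision
          row$recall <- best$recall
          row$f_score <- best$f_score
          row$enrichment_p <- gate$p_adjusted
          row$pass <- gate$pass
          if (gate$pass) {
            novel <- setdiff(top_set, rhy_here)
            combo_id <- paste(net_tag, meas, sep = ":")
            bands[[combo_id]] <- list(genes = top_set, universe = nodes,
                                      network = net_tag, measure = meas)
            support[[combo_id]] <- novel
            row$n_predicted <- length(top_set)
            row$n_novel <- length(novel)
          }
        }
      }
      combos[[length(combos) + 1]] <- row
    }
  }
  combinations <- bind_rows(combos)

  pred <- if (length(support) > 0) {
    tibble(gene_id = unlist(support, use.names = FALSE),
           combo = rep(names(support), lengths(support))) %>%
      group_by(.data$gene_id) %>%
      summarise(support = dplyr::n(),
                combinations = paste(sort(.data$combo), collapse = ";"),
                .groups = "drop") %>%
      arrange(desc(.data$support), .data$gene_id)
  } else {
    tibble(gene_id = character(), support = integer(),
           combinations = character())
  }
  structure(list(combinations = combinations, predictions = pred,
                 novel = pred$gene_id, bands = bands),
            class = "centrality_prediction")
}
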