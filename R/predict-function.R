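#' Term enrichment of a gene group
#'
#' Upper-tail hypergeometric enrichment of every term annotating at least one
#' group member, Bonferroni-corrected over the number of terms tested for the
#' group (or an explicit `n_tests`).
#'
#' @param group Gene ids (subset of `universe`).
#' @param ann Annotation tibble (`gene`, `term`).
#' @param universe Gene universe for the test.
#' @param n_tests Bonferroni factor; default = number of terms tested.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return Tibble: `term`, `n_group`, `n_universe`, `p_raw`, `p_adjusted`,
#'   `significant`.
#' @export
group_term_enrichment <- function(group, ann, universe, n_tests = NULL,
                                  alpha = 0.05) {
  if (length(group) == 0) abort("empty group")
  if (!all(group %in% universe)) abort("group must be a subset of the universe")
  ann_u <- ann[ann$gene %in% universe, ]
  in_group <- ann_u[ann_u$gene %in% group, ]
  if (nrow(in_group) == 0) {
    return(tibble(term = character(), n_group = integer(),
                  n_universe = integer(), p_raw = numeric(),
                  p_adjusted = numeric(), significant = logical()))
  }
  counts_g <- table(in_group$term)
  counts_u <- table(ann_u$term[ann_u$term %in% names(counts_g)])
  terms <- names(counts_g)
  n_tests <- n_tests %||% length(terms)
  p <- vapply(terms, function(t) {
    hyper_upper_p(counts_g[[t]], length(group), counts_u[[t]],
                  length(universe))
  }, 1)
  p_adj <- pmin(1, p * n_tests)
  tibble(term = terms, n_group = as.integer(counts_g[terms]),
         n_universe = as.integer(counts_u[terms]),
         p_raw = unname(p), p_adjusted = unname(p_adj),
         significant = unname(p_adj) < alpha) %>%
    arrange(.data$p_adjusted, .data$term)
}

#' Assemble guilt-by-association gene groups from prediction results
#'
#' The two grouping schemes used for function prediction: each passing
#' network-by-centrality combination contributes its optimal top-K band, and
#' each contributing network's significant MCL clusters are groups of their
#' own.
#'
#' @param centrality_pred A `centrality_prediction` object.
#' @param cluster_pred A `cluster_prediction` object.
#' @return `groups_by_source`: a list with elements `centrality` and
#'   `clustering`, each a list of `list(genes, universe)` groups.
#' @export
prediction_groups <- function(centrality_pred, cluster_pred) {
  cent <- purrr::map(centrality_pred$bands, function(b) {
    list(genes = b$genes, universe = b$universe)
  })
  clus <- list()
  for (tag in names(cluster_pred$clusters)) {
    entry <- cluster_pred$clusters[[tag]]
    for (ci in seq_along(entry$clusters)) {
      clus[[paste(tag, names(entry$clusters)[ci], sep = ":")]] <-
        list(genes = entry$clusters[[ci]], universe = entry$universe)
    }
  }
  list(centrality = cent, clustering = clus)
}

#' Predict gene--term associations by guilt by association
#'
#' For each source (centrality bands, MCL clusters) and each group, terms
#' significantly enriched in the group are propagated to every group member
#' that lacks them. High-confidence predictions are the intersection of the
#' two sources' pair sets. Pairs are split by whether the receiving gene has
#' any existing annotation (`characterized`) or none (`uncharacterized`).
#'
#' @param groups_by_source As from [prediction_groups()].
#' @param ann Annotation tibble (`gene`, `term`).
#' @param alpha Enrichment significance level (default 0.05).
#' @return Tibble of class `function_prediction`: `gene`, `term`,
#'   `in_centrality`, `in_clustering`, `source`, `gene_status`,
#'   `p_adjusted` (smallest supporting adjusted p).
#' @export
predict_annotations <- function(groups_by_source, ann, alpha = 0.05) {
  source_pairs <- purrr::map(groups_by_source, function(groups) {
    rows <- purrr::imap(groups, function(grp, gid) {
      enr <- group_term_enrichment(grp$genes, ann, grp$universe, alpha = alpha)
      sig <- enr[enr$significant, ]
      if (nrow(sig) == 0) return(NULL)
      purrr::map(seq_len(nrow(sig)), function(i) {
        t <- sig$term[i]
        has <- unique(ann$gene[ann$term == t])
        lacking <- setdiff(grp$genes, has)
        if (length(lacking) == 0) return(NULL)
        tibble(gene = lacking, term = t, group = gid,
               p_adjusted = sig$p_adjusted[i])
      }) %>% bind_rows()
    })
    pairs <- bind_rows(rows)
    if (nrow(pairs) == 0) return(pairs)
    pairs %>%
      group_by(.data$gene, .data$term) %>%
      summarise(p_adjusted = min(.data$p_adjusted), .groups = "drop")
  })

  all_pairs <- bind_rows(
    purrr::imap(source_pairs, function(p, src) {
      if (nrow(p) == 0) return(NULL)
      mutate(p, src = src)
    })
  )
  if (is.null(all_pairs) || nrow(all_pairs) == 0) {
    out <- tibble(gene = character(), term = character(),
                  in_centrality = logical(), in_clustering = logical(),
                  source = character(), gene_status = character(),
                  p_adjusted = numeric())
    class(out) <- c("function_prediction", class(out))
    return(out)
  }
  annotated <- unique(ann$gene)
  out <- all_pairs %>%
    group_by(.data$gene, .data$term) %>%
    summarise(in_centrality = "centrality" %in% .data$src,
              in_clustering = "clustering" %in% .data$src,
              p_adjusted = min(.data$p_adjusted), .groups = "drop") %>%
    mutate(source = case_when(
      .data$in_centrality & .data$in_clustering ~ "both",
      .data$in_centrality ~ "centrality",
      TRUE ~ "clustering"
    ),
    gene_status = ifelse(.data$gene %in% annotated, "characterized",
                         "uncharacterized")) %>%
    arrange(.data$gene, .data$term)
  class(out) <- c("function_prediction", class(out))
  out
}

#' Leave-one-out validation of function prediction
#'
#' Hides one annotated gene's annotations at a time, recomputes group
#' enrichment for the groups containing it, collects the predictions the
#' intersection of the two sources would make for that gene, and scores them
#' against the hidden truth. Precision is pooled over all predicted pairs.
#'
#' @param groups_by_source As from [prediction_groups()].
#' @param ann Annotation tibble.
#' @param alpha Enrichment significance level (default 0.05).
#' @return One-row tibble: `n_genes_evaluated`, `n_predicted_pairs`,
#'   `n_correct_pairs`, `precision`.
#' @export
loocv_precision <- function(groups_by_source, ann, alpha = 0.05) {
  annotated <- unique(ann$gene)
  if (length(annotated) < 2) abort("need at least 2 annotated genes")
  ann_by_gene <- split(ann$term, ann$gene)

  # genes in at least one group of each source can receive intersection
  # predictions; all annotated genes in any group are evaluated
  in_source <- purrr::map(groups_by_source, function(groups) {
    unique(unlist(purrr::map(groups, "genes")))
  })
  eval_genes <- intersect(annotated, unique(unlist(in_source)))

  n_pred <- 0L
  n_corr <- 0L
  for (g in eval_genes) {
    hidden_terms <- ann_by_gene[[g]]
    ann_minus <- ann[ann$gene != g, ]
    per_source <- purrr::map(groups_by_source, function(groups) {
      terms <- character()
      for (grp in groups) {
        if (!g %in% grp$genes) next
        enr <- group_term_enrichment(grp$genes, ann_minus, grp$universe,
                                     alpha = alpha)
        terms <- union(terms, enr$term[enr$significant])
      }
      terms
    })
    predicted <- Reduce(intersect, per_source)
    n_pred <- n_pred + length(predicted)
    n_corr <- n_corr + length(intersect(predicted, hidden_terms))
  }
  tibble(
    n_genes_evaluated = length(eval_genes),
    n_predicted_pairs = n_pred,
    n_correct_pairs = n_corr,
    precision = if (n_pred > 0) n_corr / n_pred else NA_real_
  )
}
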