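#' Significance of the overlap between two gene sets
#'
#' Exact upper-tail hypergeometric p-value of the observed overlap, given a
#' gene universe.
#'
#' @param a,b Gene-id vectors (subsets of `universe`).
#' @param universe Gene universe.
#' @return One-row tibble of class `overlap_test`: set sizes, universe size,
#'   overlap, `p_value` and `percent_overlap` (overlap / |a|).
#' @export
overlap_significance <- function(a, b, universe) {
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  if (!all(a %in% universe) || !all(b %in% universe)) {
    abort("sets must be subsets of the universe")
  }
  ov <- length(intersect(a, b))
  out <- tibble(
    set_a_size = length(a), set_b_size = length(b),
    universe_size = length(universe), overlap = ov,
    p_value = hyper_upper_p(ov, length(a), length(b), length(universe)),
    percent_overlap = if (length(a) > 0) 100 * ov / length(a) else NA_real_
  )
  class(out) <- c("overlap_test", class(out))
  out
}

#' Validate prediction sets against a reference rhythmic-gene list
#'
#' Overlap tests of each prediction set (and useful controls) against a
#' reference list of known rhythmic genes, restricted to the network
#' universe. Reference genes outside the universe are ignored; if none
#' remain, that test is skipped with a warning.
#'
#' @param prediction_sets Named list of gene-id vectors (e.g. centrality
#'   novel, cluster novel, their intersection, the scan-identified set, and a
#'   negative control).
#' @param reference Reference rhythmic gene ids.
#' @param universe Network gene universe.
#' @return Tibble: one overlap test per prediction set.
#' @export
reference_set_validation <- function(prediction_sets, reference, universe) {
  ref <- intersect(reference, universe)
  if (length(ref) == 0) {
    warn("reference set is empty after restriction to the universe; skipped")
    return(tibble(set = character()))
  }
  purrr::imap(prediction_sets, function(genes, nm) {
    genes <- intersect(genes, universe)
    if (length(genes) == 0) {
      return(tibble(set = nm, set_a_size = 0L, set_b_size = length(ref),
                    universe_size = length(unique(universe)), overlap = 0L,
                    p_value = 1, percent_overlap = NA_real_))
    }
    mutate(overlap_significance(genes, ref, universe), set = nm,
           .before = 1)
  }) %>% bind_rows()
}

#' Overlap of enriched terms between gene sets
#'
#' Computes the enriched-term set of each of three disjoint gene sets
#' (positives, predictions, negative controls) and then the pairwise
#' hypergeometric overlap of those term sets over the universe of terms
#' tested in any of the three.
#'
#' @param positive,predicted,negative Disjoint gene-id vectors.
#' @param ann Annotation tibble.
#' @param universe Gene universe for the enrichment tests.
#' @param alpha Enrichment significance level (default 0.05).
#' @return A list: `enriched` (named list of enriched term vectors) and
#'   `overlaps` (tibble of pairwise term-set overlap tests).
#' @export
enriched_term_overlap <- function(positive, predicted, negative, ann,
                                  universe, alpha = 0.05) {
  sets <- list(positive = positive, predicted = predicted,
               negative = negative)
  nonempty <- names(sets)[lengths(sets) > 0]
  if (length(intersect(positive, predicted)) > 0 ||
      length(intersect(positive, negative)) > 0 ||
      length(intersect(predicted, negative)) > 0) {
    abort("input gene sets must be disjoint")
  }
  enr <- purrr::map(sets[nonempty], function(s) {
    group_term_enrichment(s, ann, universe, alpha = alpha)
  })
  enriched <- purrr::map(enr, function(e) e$term[e$significant])
  tested <- unique(unlist(purrr::map(enr, "term")))
  pairs <- combn(names(enriched), 2)
  overlaps <- purrr::map(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    if (length(tested) == 0) {
      return(tibble(sets = paste(a, b, sep = " vs "), overlap = 0L,
                    p_value = 1))
    }
    ot <- overlap_significance(enriched[[a]], enriched[[b]], tested)
    mutate(ot, sets = paste(a, b, sep = " vs "), .before = 1)
  }) %>% bind_rows()
  list(enriched = enriched, overlaps = overlaps)
}

#' Overlap of a differential-expression set with the rhythmic set
#'
#' Count and percentage of genes both differentially expressed under a
#' treatment condition and rhythmically expressed, as used in
#' condition-comparison tables.
#'
#' @param de_set Differentially expressed gene ids (non-empty).
#' @param rhythmic Rhythmic gene ids.
#' @param universe Gene universe (both sets must lie within it).
#' @return One-row tibble: `n_de`, `n_overlap`, `percent` (rounded to the
#'   nearest whole percent).
#' @export
condition_overlap <- function(de_set, rhythmic, universe) {
  de_set <- unique(de_set); rhythmic <- unique(rhythmic)
  if (length(de_set) == 0) abort("empty differential-expression set")
  if (!all(de_set %in% universe) || !all(rhythmic %in% universe)) {
    abort("sets must be subsets of the universe")
  }
  ov <- length(intersect(de_set, rhythmic))
  tibble(n_de = length(de_set), n_overlap = ov,
         percent = round(100 * ov / length(de_set)))
}
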