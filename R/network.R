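#' Pairwise co-expression scores
#'
#' Scores every unordered gene pair by one of three edge-weight methods:
#' signed Pearson correlation (`r`), absolute Pearson correlation (`|r|`), or
#' plug-in mutual information in bits after per-gene equal-width binning.
#' Genes with zero variance are excluded from Pearson scoring with a warning;
#' for mutual information a constant gene simply occupies a single bin.
#'
#' @param x Expression tibble of profiles (typically the per-timepoint means
#'   from [collapse_replicates()]).
#' @param method One of `"signed_pearson"`, `"abs_pearson"`,
#'   `"mutual_information"`.
#' @param bins Number of equal-width bins per gene for mutual information
#'   (default 3, the coarsest informative choice for 12-point profiles).
#' @return A `coexpr_scores` object: symmetric score matrix over the
#'   lexicographically sorted scored genes plus the method tag.
#' @export
coexpression_scores <- function(x, method = c("signed_pearson", "abs_pearson",
                                              "mutual_information"),
                                bins = 3) {
  method <- match.arg(method)
  pm <- profile_matrix(x)
  m <- pm$values
  if (ncol(m) < 3) abort("need >= 3 profile points per gene")
  m <- m[sort(rownames(m), method = "radix"), , drop = FALSE]

  if (method %in% c("signed_pearson", "abs_pearson")) {
    v <- apply(m, 1, sd)
    if (any(v == 0)) {
      warn(sprintf("%d zero-variance gene(s) excluded from Pearson scoring",
                   sum(v == 0)))
      m <- m[v > 0, , drop = FALSE]
    }
    s <- cor(t(m))
    if (method == "abs_pearson") s <- abs(s)
  } else {
    if (bins < 2) abort("`bins` must be >= 2")
    if (ncol(m) < bins) abort("profiles must have at least `bins` points")
    s <- mi_matrix(m, bins)
  }
  diag(s) <- NA_real_
  structure(list(score = s, method = method, genes = rownames(m)),
            class = "coexpr_scores")
}

# per-gene equal-width binning into 1..bins
bin_profiles <- function(m, bins) {
  rng <- apply(m, 1, range)
  lo <- rng[1, ]; hi <- rng[2, ]
  width <- hi - lo
  width[width == 0] <- 1         # constant gene: everything lands in bin 1
  b <- floor((m - lo) / width * bins) + 1
  b[b > bins] <- bins
  storage.mode(b) <- "integer"
  b
}

# all-pairs plug-in MI (bits) via indicator-matrix cross-products
mi_matrix <- function(m, bins) {
  b <- bin_profiles(m, bins)
  n_t <- ncol(m)
  ind <- lapply(seq_len(bins), function(k) (b == k) * 1)
  marg <- vapply(ind, rowSums, numeric(nrow(m))) / n_t  # genes x bins
  mi <- matrix(0, nrow(m), nrow(m))
  for (a in seq_len(bins)) {
    for (bb in seq_len(bins)) {
      pab <- (ind[[a]] %*% t(ind[[bb]])) / n_t
      denom <- outer(marg[, a], marg[, bb])
      term <- pab * log2(pab / denom)
      term[pab == 0] <- 0
      mi <- mi + term
    }
  }
  mi[mi < 0] <- 0                 # guard tiny negative rounding
  dimnames(mi) <- list(rownames(m), rownames(m))
  mi
}

#' Mutual information of two vectors
#'
#' Plug-in estimate (bits) of the joint histogram after per-vector equal-width
#' binning.
#'
#' @param x,y Equal-length numeric vectors.
#' @param bins Number of equal-width bins (>= 2).
#' @return Non-negative mutual information in bits.
#' @export
mutual_information <- function(x, y, bins = 3) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal lengths")
  if (bins < 2) abort("`bins` must be >= 2")
  if (length(x) < bins) abort("vectors must have at least `bins` values")
  m <- rbind(x = x, y = y)
  mi_matrix(m, bins)["x", "y"]
}

#' Tidy pairwise scores
#'
#' @param x Expression tibble.
#' @inheritParams coexpression_scores
#' @return Tibble with `gene_a < gene_b` (lexicographic) and `score`.
#' @export
score_pairs <- function(x, method = "signed_pearson", bins = 3) {
  sc <- coexpression_scores(x, method, bins)
  ut <- upper.tri(sc$score)
  idx <- which(ut, arr.ind = TRUE)
  tibble(gene_a = sc$genes[idx[, 1]], gene_b = sc$genes[idx[, 2]],
         score = sc$score[ut]) %>%
    arrange(.data$gene_a, .data$gene_b)
}

new_coexpr_network <- function(graph, method_tag, k_multiplier, universe) {
  structure(list(graph = graph, method_tag = method_tag,
                 k_multiplier = k_multiplier, universe = universe),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf("Co-expression network [%s, K = %sN]: %d nodes (%d non-isolated), %d edges\n",
              x$method_tag, format(x$k_multiplier), igraph::vcount(x$graph),
              sum(igraph::degree(x$graph) > 0), igraph::ecount(x$graph)))
  invisible(x)
}

#' Build a top-K co-expression network
#'
#' Keeps the `K = k_multiplier * N` highest-scoring gene pairs as edges
#' (`N` = number of scored genes). Ties at the threshold are broken by
#' lexicographic pair id so the edge count is exactly `K`. Isolated genes are
#' kept as nodes so summary counts can report them.
#'
#' @param scores A `coexpr_scores` object.
#' @param k_multiplier Edge-budget multiplier (`K = k_multiplier * N`).
#' @param method_tag Optional label stored on the network.
#' @return A `coexpr_network`.
#' @export
build_network <- function(scores, k_multiplier, method_tag = NULL) {
  if (!inherits(scores, "coexpr_scores")) abort("`scores` must be coexpr_scores")
  genes <- scores$genes
  n <- length(genes)
  k <- round(k_multiplier * n)
  ut <- upper.tri(scores$score)
  idx <- which(ut, arr.ind = TRUE)
  v <- scores$score[ut]
  n_pairs <- length(v)
  if (k >= n_pairs) {
    if (k > n_pairs) warn("edge budget K exceeds the number of pairs; building the complete graph")
    sel <- seq_len(n_pairs)
  } else if (k <= 0) {
    sel <- integer()
  } else {
    thr <- -sort(-v, partial = k)[k]
    above <- which(v > thr)
    tied <- which(v == thr)
    need <- k - length(above)
    tied <- tied[order(idx[tied, 1], idx[tied, 2])][seq_len(need)]
    sel <- c(above, tied)
  }
  edges <- tibble(gene_a = genes[idx[sel, 1]], gene_b = genes[idx[sel, 2]],
                  weight = v[sel]) %>%
    arrange(.data$gene_a, .data$gene_b)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = genes)
  new_coexpr_network(g, method_tag %||% scores$method, k_multiplier, genes)
}

network_edges <- function(net) {
  e <- igraph::as_data_frame(net$graph, what = "edges")
  a <- pmin(e$from, e$to); b <- pmax(e$from, e$to)
  tibble(gene_a = a, gene_b = b,
         weight = if ("weight" %in% names(e)) e$weight else rep(1, nrow(e))) %>%
    arrange(.data$gene_a, .data$gene_b)
}

#' Intersect two co-expression networks
#'
#' Edge set = intersection of the two edge sets (weights taken from `a`);
#' isolated nodes are dropped from the result.
#'
#' @param a,b `coexpr_network` objects over the same gene universe.
#' @param method_tag Label for the result.
#' @return A `coexpr_network`.
#' @export
intersect_networks <- function(a, b, method_tag = NULL) {
  if (!identical(sort(a$universe), sort(b$universe))) {
    abort("networks are defined over different gene universes")
  }
  ea <- network_edges(a); eb <- network_edges(b)
  key_a <- paste(ea$gene_a, ea$gene_b, sep = "\r")
  key_b <- paste(eb$gene_a, eb$gene_b, sep = "\r")
  keep <- ea[key_a %in% key_b, ]
  nodes <- sort(unique(c(keep$gene_a, keep$gene_b)))
  g <- igraph::graph_from_data_frame(keep, directed = FALSE, vertices = nodes)
  new_coexpr_network(g, method_tag %||% paste0(a$method_tag, "&", b$method_tag),
                     min(a$k_multiplier, b$k_multiplier), a$universe)
}

#' Largest connected component
#'
#' Induced subgraph on the largest connected node set; among equally large
#' components the one containing the lexicographically smallest node id wins.
#'
#' @param net A `coexpr_network`.
#' @return A `coexpr_network` restricted to the largest component.
#' @export
largest_component <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0) abort("empty network")
  comp <- igraph::components(g)
  max_size <- max(comp$csize)
  cand <- which(comp$csize == max_size)
  if (length(cand) > 1) {
    smallest <- vapply(cand, function(ci) {
      min(igraph::V(g)$name[comp$membership == ci])
    }, character(1))
    cand <- cand[order(smallest)][1]
  }
  keep <- igraph::V(g)$name[comp$membership == cand]
  sub <- igraph::induced_subgraph(g, keep)
  out <- new_coexpr_network(sub, net$method_tag, net$k_multiplier, net$universe)
  out
}

#' Network summary counts
#'
#' One-row tibble: non-isolated nodes, edges, connected components (among
#' non-isolated nodes), nodes and edges of the largest component, and density
#' over the non-isolated node set.
#'
#' @param x A `coexpr_network`.
#' @param ... Unused.
#' @method glance coexpr_network
#' @export
glance.coexpr_network <- function(x, ...) {
  g <- x$graph
  deg <- igraph::degree(g)
  non_iso <- names(deg)[deg > 0]
  n <- length(non_iso)
  if (n == 0) {
    return(tibble(n_nodes = 0L, n_edges = 0L, n_components = 0L,
                  lcc_nodes = 0L, lcc_edges = 0L, density = 0))
  }
  sub <- igraph::induced_subgraph(g, non_iso)
  comp <- igraph::components(sub)
  lcc_id <- which.max(comp$csize)
  lcc <- igraph::induced_subgraph(sub, names(comp$membership)[comp$membership == lcc_id])
  tibble(
    n_nodes = n,
    n_edges = igraph::ecount(sub),
    n_components = comp$no,
    lcc_nodes = igraph::vcount(lcc),
    lcc_edges = igraph::ecount(lcc),
    density = if (n > 1) igraph::ecount(sub) / choose(n, 2) else 0
  )
}

#' @method tidy coexpr_network
#' @export
tidy.coexpr_network <- function(x, ...) network_edges(x)

#' Build the standard five co-expression networks
#'
#' The package's default network panel: signed Pearson, absolute Pearson and
#' mutual information each with a top-`N` edge budget, plus the intersections
#' of absolute Pearson and mutual information at top-`10N` and top-`25N`
#' budgets.
#'
#' @param x Expression profile tibble (per-timepoint means).
#' @param bins Mutual-information bin count.
#' @return Named list of `coexpr_network` objects:
#'   `SIGN_N`, `ABS_N`, `MI_N`, `ABS_MI_10N`, `ABS_MI_25N`.
#' @export
build_standard_networks <- function(x, bins = 3) {
  sgn <- coexpression_scores(x, "signed_pearson", bins)
  abs_s <- sgn
  abs_s$score <- abs(abs_s$score)
  abs_s$method <- "abs_pearson"
  mi <- coexpression_scores(x, "mutual_information", bins)
  # genes excluded from one scoring scheme (e.g. zero variance under
  # Pearson) are dropped from all networks so the panel shares one universe
  common <- intersect(sgn$genes, mi$genes)
  restrict <- function(sc) {
    if (length(sc$genes) == length(common)) return(sc)
    sc$score <- sc$score[common, common, drop = FALSE]
    sc$genes <- common
    sc
  }
  sgn <- restrict(sgn); abs_s <- restrict(abs_s); mi <- restrict(mi)
  list(
    SIGN_N = build_network(sgn, 1, "SIGN_N"),
    ABS_N = build_network(abs_s, 1, "ABS_N"),
    MI_N = build_network(mi, 1, "MI_N"),
    ABS_MI_10N = intersect_networks(build_network(abs_s, 10, "ABS_10N"),
                                    build_network(mi, 10, "MI_10N"),
                                    "ABS_MI_10N"),
    ABS_MI_25N = intersect_networks(build_network(abs_s, 25, "ABS_25N"),
                                    build_network(mi, 25, "MI_25N"),
                                    "ABS_MI_25N")
  )
}

#' Pairwise edge-set overlaps between networks
#'
#' @param nets Named list of `coexpr_network` objects.
#' @return Tibble of pairwise edge overlaps and Jaccard indices.
#' @export
network_edge_overlap <- function(nets) {
  keys <- purrr::map(nets, function(n) {
    e <- network_edges(n)
    paste(e$gene_a, e$gene_b, sep = "\r")
  })
  pairs <- combn(names(nets), 2)
  purrr::map(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    ov <- length(intersect(keys[[a]], keys[[b]]))
    un <- length(union(keys[[a]], keys[[b]]))
    tibble(net_a = a, net_b = b, edges_a = length(keys[[a]]),
           edges_b = length(keys[[b]]), overlap = ov,
           jaccard = if (un > 0) ov / un else 0)
  }) %>% bind_rows()
}
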