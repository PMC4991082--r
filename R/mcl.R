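#' Markov clustering (MCL)
#'
#' Iterates expansion (matrix squaring) and inflation (elementwise power with
#' column renormalization) on the self-loop-augmented column-stochastic
#' adjacency matrix until the maximum entry change falls below `tol` or
#' `max_iter` is reached. Edge weights are ignored (binary adjacency with unit
#' self-loops); entries below `prune` are dropped each iteration to keep the
#' matrix sparse. Clusters are the weakly connected components of the
#' converged matrix's support, which always partition the node set; clusters
#' are labelled in order of their lexicographically smallest member.
#'
#' @param net A `coexpr_network` or igraph object.
#' @param inflation Inflation exponent (default 2, a granularity that gives a
#'   balanced cluster-size distribution on co-expression graphs).
#' @param tol Convergence tolerance on the max entry change (default 1e-6).
#' @param max_iter Maximum iterations (default 200); if reached, the current
#'   interpretation is returned with attribute `converged = FALSE` and a
#'   warning.
#' @param prune Entries below this are zeroed each iteration (default 1e-8).
#' @return A tibble of class `mcl_clustering` with columns `gene_id` and
#'   `cluster` (integer ids).
#' @export
mcl_cluster <- function(net, inflation = 2, tol = 1e-6, max_iter = 200,
                        prune = 1e-8) {
  g <- if (inherits(net, "coexpr_network")) net$graph else net
  n <- igraph::vcount(g)
  if (n == 0) abort("empty network")
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))

  a <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  a@x[] <- 1                                   # binary
  m <- a + Matrix::Diagonal(n)
  m <- col_normalize(m)

  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m2 <- m %*% m                              # expansion
    m2@x <- m2@x^inflation                     # inflation
    m2 <- Matrix::drop0(m2, tol = prune)
    m2 <- col_normalize(m2)
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warn("MCL did not converge within max_iter; returning current state")

  # clusters = weakly connected components of the support
  supp <- as(m, "TsparseMatrix")
  gg <- igraph::graph_from_data_frame(
    data.frame(from = supp@i + 1, to = supp@j + 1),
    directed = FALSE, vertices = data.frame(name = seq_len(n))
  )
  memb <- igraph::components(gg)$membership

  # relabel clusters by their lexicographically smallest member
  k <- max(memb)
  smallest <- vapply(seq_len(k), function(ci) min(nodes[memb == ci]), character(1))
  relabel <- integer(k)
  relabel[order(smallest)] <- seq_len(k)
  out <- tibble(gene_id = nodes, cluster = relabel[memb])
  class(out) <- c("mcl_clustering", class(out))
  attr(out, "converged") <- converged
  attr(out, "inflation") <- inflation
  out
}

col_normalize <- function(m) {
  cs <- Matrix::colSums(m)
  cs[cs == 0] <- 1
  m %*% Matrix::Diagonal(x = 1 / cs)
}

#' @method glance mcl_clustering
#' @export
glance.mcl_clustering <- function(x, ...) {
  sizes <- table(x$cluster)
  tibble(n_clusters = length(sizes),
         largest = max(sizes),
         median_size = median(as.integer(sizes)),
         n_singletons = sum(sizes == 1),
         converged = isTRUE(attr(x, "converged")))
}
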