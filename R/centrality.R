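CENTRALITY_MEASURES <- c("betweenness", "closeness", "clustering_coefficient",
                         "degree", "eccentricity", "graphlet_degree",
                         "k_coreness")

#' Graphlet orbit counts
#'
#' Per-node counts of the 15 automorphism orbits of the connected 2--4-node
#' graphlets (orbit 0 = degree, orbit 3 = triangle membership, orbit 14 = K4
#' membership, ...), via exhaustive enumeration of connected induced
#' subgraphs.
#'
#' @param net A `coexpr_network` (or igraph object).
#' @return Integer matrix, one row per node (named), 15 orbit columns.
#' @export
graphlet_orbit_counts <- function(net) {
  g <- if (inherits(net, "coexpr_network")) net$graph else net
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  counts <- count_graphlet_orbits(igraph::vcount(g),
                                  matrix(as.integer(el - 1), ncol = 2))
  rownames(counts) <- nodes
  colnames(counts) <- paste0("orbit_", 0:14)
  counts
}

# Orbit dependency counts o_i: orbits of connected induced subgraphs of the
# orbit's own graphlet that contain the orbit node. Derived programmatically
# from representative graphlets, giving weights w_i = 1 - log(o_i)/log(15).
graphlet_orbit_weights <- function() {
  cached <- dielnet_env$orbit_weights
  if (!is.null(cached)) return(cached)
  # representative graphlets as edge lists on nodes 1..k, with the orbit of
  # each node
  reps <- list(
    list(edges = rbind(c(1, 2)), orbits = c(0, 0)),
    list(edges = rbind(c(1, 2), c(2, 3)), orbits = c(1, 2, 1)),
    list(edges = rbind(c(1, 2), c(2, 3), c(1, 3)), orbits = c(3, 3, 3)),
    list(edges = rbind(c(1, 2), c(2, 3), c(3, 4)), orbits = c(4, 5, 5, 4)),
    list(edges = rbind(c(1, 2), c(1, 3), c(1, 4)), orbits = c(7, 6, 6, 6)),
    list(edges = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)),
         orbits = c(8, 8, 8, 8)),
    list(edges = rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4)),
         orbits = c(11, 10, 10, 9)),
    list(edges = rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(3, 4)),
         orbits = c(13, 12, 13, 12)),
    list(edges = rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4)),
         orbits = c(14, 14, 14, 14))
  )
  orbit_of_subgraph <- function(adj, node) {
    k <- nrow(adj)
    deg <- rowSums(adj)
    m <- sum(adj) / 2
    if (k == 2) return(0)
    if (k == 3) {
      if (m == 3) return(3)
      return(if (deg[node] == 2) 2 else 1)
    }
    if (m == 3) {
      if (max(deg) == 3) return(if (deg[node] == 3) 7 else 6)
      return(if (deg[node] == 2) 5 else 4)
    }
    if (m == 4) {
      if (all(deg == 2)) return(8)
      return(c(9, 10, 11)[deg[node]])
    }
    if (m == 5) return(if (deg[node] == 3) 13 else 12)
    14
  }
  deps <- integer(15)
  for (rep_g in reps) {
    k <- max(rep_g$edges)
    adj <- matrix(0, k, k)
    adj[rep_g$edges] <- 1
    adj[rep_g$edges[, 2:1, drop = FALSE]] <- 1
    for (v in seq_len(k)) {
      found <- integer()
      for (size in 2:k) {
        for (s in combn(k, size, simplify = FALSE)) {
          if (!v %in% s) next
          sub <- adj[s, s, drop = FALSE]
          # connected?
          reach <- 1; repeat {
            nxt <- unique(c(reach, which(colSums(sub[reach, , drop = FALSE]) > 0)))
            if (length(nxt) == length(reach)) break
            reach <- nxt
          }
          if (length(reach) < size) next
          found <- union(found, orbit_of_subgraph(sub, match(v, s)))
        }
      }
      deps[rep_g$orbits[v] + 1] <- length(found)
    }
  }
  w <- 1 - log(deps) / log(15)
  dielnet_env$orbit_weights <- w
  w
}

dielnet_env <- new.env(parent = emptyenv())

#' Graphlet degree centrality
#'
#' Weighted combination of a node's graphlet orbit counts:
#' `sum_i w_i * log(d_i + 1)` over the 15 orbits, with weights
#' `w_i = 1 - log(o_i)/log(15)` where `o_i` counts the orbits the i-th orbit
#' depends on, so redundant deep orbits contribute less.
#'
#' @param net A `coexpr_network` or igraph object.
#' @return Named numeric vector of centralities.
#' @export
graphlet_degree <- function(net) {
  counts <- graphlet_orbit_counts(net)
  w <- graphlet_orbit_weights()
  drop(log(counts + 1) %*% w)
}

#' Node centralities
#'
#' Computes the requested centrality measures on a connected network:
#' betweenness (unnormalized shortest-path counts), closeness
#' (`(n-1)/sum(d)`), local clustering coefficient (0 for degree < 2),
#' degree, eccentricity, graphlet degree centrality and k-coreness.
#'
#' @param net A connected `coexpr_network` (use [largest_component()] first).
#' @param measures Subset of
#'   `c("betweenness", "closeness", "clustering_coefficient", "degree",
#'   "eccentricity", "graphlet_degree", "k_coreness")`.
#' @return Tibble with `gene_id` and one column per measure.
#' @export
node_centrality <- function(net, measures = CENTRALITY_MEASURES) {
  measures <- match.arg(measures, CENTRALITY_MEASURES, several.ok = TRUE)
  g <- if (inherits(net, "coexpr_network")) net$graph else net
  if (igraph::vcount(g) == 0) abort("empty network")
  if (igraph::components(g)$no > 1) {
    abort("network is disconnected; run largest_component() first")
  }
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  out <- tibble(gene_id = nodes)
  for (m in measures) {
    out[[m]] <- switch(
      m,
      betweenness = unname(igraph::betweenness(g, directed = FALSE,
                                               weights = NA)),
      closeness = if (igraph::vcount(g) == 1) 0 else
        unname(igraph::closeness(g, normalized = TRUE, weights = NA)),
      clustering_coefficient = {
        cc <- unname(igraph::transitivity(g, type = "local",
                                          isolates = "zero"))
        cc[is.na(cc)] <- 0
        cc
      },
      degree = unname(igraph::degree(g)),
      eccentricity = unname(igraph::eccentricity(g, weights = NA)),
      graphlet_degree = unname(graphlet_degree(g)),
      k_coreness = unname(igraph::coreness(g))
    )
  }
  out
}
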