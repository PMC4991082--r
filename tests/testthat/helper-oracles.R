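# Brute-force centrality oracles, written independently of the package
# implementation (plain adjacency-matrix algorithms, exhaustive subgraph
# enumeration for graphlet orbits).

oracle_adjacency <- function(g) {
  n <- igraph::vcount(g)
  a <- matrix(0L, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) > 0) {
    a[el] <- 1L
    a[el[, 2:1, drop = FALSE]] <- 1L
  }
  a
}

# all-pairs BFS distances and shortest-path counts
oracle_paths <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n); diag(d) <- 0
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  for (s in seq_len(n)) {
    frontier <- s
    dist <- 0
    while (length(frontier) > 0) {
      nxt <- integer()
      for (v in frontier) {
        for (u in which(a[v, ] == 1L)) {
          if (is.infinite(d[s, u])) {
            d[s, u] <- dist + 1
            nxt <- c(nxt, u)
          }
          if (d[s, u] == dist + 1) sigma[s, u] <- sigma[s, u] + sigma[s, v]
        }
      }
      frontier <- unique(nxt)
      dist <- dist + 1
    }
  }
  list(d = d, sigma = sigma)
}

oracle_betweenness <- function(a) {
  n <- nrow(a)
  p <- oracle_paths(a)
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || is.infinite(p$d[s, t])) next
        if (p$d[s, v] + p$d[v, t] == p$d[s, t]) {
          b[v] <- b[v] + p$sigma[s, v] * p$sigma[v, t] / p$sigma[s, t]
        }
      }
    }
  }
  b
}

oracle_closeness <- function(a) {
  n <- nrow(a)
  if (n == 1) return(0)
  d <- oracle_paths(a)$d
  vapply(seq_len(n), function(v) (n - 1) / sum(d[v, -v]), 1)
}

oracle_eccentricity <- function(a) {
  d <- oracle_paths(a)$d
  apply(d, 1, max)
}

oracle_clustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(v) {
    nb <- which(a[v, ] == 1L)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(a[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, 1)
}

oracle_coreness <- function(a) {
  n <- nrow(a)
  alive <- rep(TRUE, n)
  core <- integer(n)
  k <- 0
  while (any(alive)) {
    repeat {
      deg <- rowSums(a[, alive, drop = FALSE])[alive]
      drop_v <- which(alive)[deg < k]
      if (length(drop_v) == 0) break
      core[drop_v] <- k - 1
      alive[drop_v] <- FALSE
    }
    if (!any(alive)) break
    k <- k + 1
  }
  core
}

# orbit of `node` within a connected induced subgraph given by adjacency
# `sub` (2-4 nodes), classified from first principles by size, edge count and
# degree sequence
oracle_orbit <- function(sub, node) {
  k <- nrow(sub)
  deg <- rowSums(sub)
  m <- sum(sub) / 2
  if (k == 2) return(0L)
  if (k == 3) {
    if (m == 3) return(3L)                      # triangle
    return(if (deg[node] == 2) 2L else 1L)      # path centre / end
  }
  # k == 4
  if (m == 3) {
    if (max(deg) == 3) return(if (deg[node] == 3) 7L else 6L)  # claw
    return(if (deg[node] == 2) 5L else 4L)                     # path
  }
  if (m == 4) {
    if (all(deg == 2)) return(8L)               # cycle
    return(c(9L, 10L, 11L)[deg[node]])          # paw: pendant/side/hub
  }
  if (m == 5) return(if (deg[node] == 3) 13L else 12L)         # diamond
  14L                                            # K4
}

oracle_graphlet_orbits <- function(a) {
  n <- nrow(a)
  counts <- matrix(0L, n, 15)
  counts[, 1] <- as.integer(rowSums(a))          # orbit 0 = degree
  is_connected_sub <- function(sub) {
    reach <- 1
    repeat {
      nxt <- unique(c(reach,
                      which(colSums(sub[reach, , drop = FALSE]) > 0)))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    length(reach) == nrow(sub)
  }
  for (size in c(3, 4)) {
    if (n < size) next
    for (s in combn(n, size, simplify = FALSE)) {
      sub <- a[s, s, drop = FALSE]
      if (!is_connected_sub(sub)) next
      for (i in seq_along(s)) {
        o <- oracle_orbit(sub, i)
        counts[s[i], o + 1] <- counts[s[i], o + 1] + 1L
      }
    }
  }
  counts
}

# orbit dependency counts o_i, tabulated by hand from the 9 connected
# 2-4-node graphlets: o_i = number of distinct orbits among connected induced
# subgraphs (containing the orbit node) of the orbit's graphlet
ORACLE_ORBIT_DEPS <- c(1, 2, 2, 2, 3, 4, 3, 3, 4, 3, 4, 4, 4, 4, 3)

oracle_graphlet_degree <- function(a) {
  counts <- oracle_graphlet_orbits(a)
  w <- 1 - log(ORACLE_ORBIT_DEPS) / log(15)
  drop(log(counts + 1) %*% w)
}

oracle_centralities <- function(g) {
  a <- oracle_adjacency(g)
  tibble::tibble(
    betweenness = oracle_betweenness(a),
    closeness = oracle_closeness(a),
    clustering_coefficient = oracle_clustering(a),
    degree = as.numeric(rowSums(a)),
    eccentricity = oracle_eccentricity(a),
    graphlet_degree = oracle_graphlet_degree(a),
    k_coreness = as.numeric(oracle_coreness(a))
  )
}

# all n! permutations of 1..n as rows of a matrix (recursive enumeration)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

# all connected graphs with at most `max_nodes` nodes from the igraph atlas
atlas_connected_graphs <- function(max_nodes = 7, min_nodes = 2) {
  out <- list()
  for (i in 1:1252) {
    g <- igraph::graph_from_atlas(i)
    n <- igraph::vcount(g)
    if (n < min_nodes || n > max_nodes) next
    if (igraph::components(g)$no != 1) next
    out[[length(out) + 1]] <- g
  }
  out
}
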