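# shared fixtures for the test suite

# two 3-cliques joined by a single bridge edge; MCL at inflation 2 must
# recover the two triangles
two_triangle_network <- function() {
  edges <- tibble::tribble(
    ~from, ~to,
    "a", "b", "b", "c", "a", "c",
    "d", "e", "e", "f", "d", "f",
    "c", "d"
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  structure(list(graph = g, method_tag = "FIXTURE", k_multiplier = NA_real_,
                 universe = sort(igraph::V(g)$name)),
            class = "coexpr_network")
}

# wrap an igraph graph as a coexpr_network (for oracle comparisons)
as_fixture_network <- function(g, tag = "FIXTURE") {
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  structure(list(graph = g, method_tag = tag, k_multiplier = NA_real_,
                 universe = igraph::V(g)$name),
            class = "coexpr_network")
}

# small deterministic expression table: n genes, given times/replicates
tiny_expression <- function(n_genes = 5, times = seq(0, 20, 4), reps = 2,
                            seed = 1) {
  withr::with_seed(seed, {
    labs <- dielnet:::format_zt_label(rep(times, each = reps),
                                      rep(seq_len(reps), length(times)))
    m <- matrix(2^rnorm(n_genes * length(labs), 10, 1), nrow = n_genes,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)), labs))
    dielnet:::expr_from_matrix(m)
  })
}
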