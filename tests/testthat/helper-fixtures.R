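# Shared fixtures and independent oracles, all built in code at test time.

tiny_panel <- function(n = 8, seed = 7) generate_panel(n, seed = seed)

# Small, fast cell: even abundance over the panel, reduced pixel lattice.
even_spec <- function(panel, total = 800, n_pix = 120, patterns = list(),
                      ...) {
  ab <- stats::setNames(rep(total / nrow(panel$markers),
                            nrow(panel$markers)),
                        panel$markers$marker)
  cell_spec(ab, patterns = patterns, n_pixels_a = n_pix, n_pixels_b = n_pix,
            ...)
}

# Brute-force Moran's I: explicit double sum over the row-normalised
# adjacency, independent of the package's sparse-matrix path.
brute_moran <- function(graph, x) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  W <- A / rowSums(A)
  N <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(N)) {
    for (j in seq_len(N)) num <- num + W[i, j] * z[i] * z[j]
  }
  (N / sum(W)) * num / sum(z^2)
}

# Brute-force one-mode projection: A-node pairs sharing >= 1 B neighbour.
brute_projection_pairs <- function(edges) {
  by_b <- split(edges$upia, edges$upib)
  pairs <- character(0)
  for (as in by_b) {
    as <- unique(as)
    if (length(as) < 2) next
    cmb <- utils::combn(sort(as), 2)
    pairs <- c(pairs, paste(cmb[1, ], cmb[2, ]))
  }
  sort(unique(pairs))
}

# Random connected simple graph for Moran oracles.
random_connected_graph <- function(n, p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::components(g)$no == 1 && min(igraph::degree(g)) > 0) {
      return(g)
    }
  }
}

# Edge tibble of a complete bipartite block with given node label prefixes.
block_edges <- function(na, nb, a_prefix = "A", b_prefix = "B",
                        marker = "CD3") {
  a <- sprintf("%s%02d", a_prefix, seq_len(na))
  b <- sprintf("%s%02d", b_prefix, seq_len(nb))
  grid <- expand.grid(upia = a, upib = b, stringsAsFactors = FALSE)
  tibble::tibble(upia = grid$upia, upib = grid$upib, marker = marker,
                 umi = sprintf("U%05d", seq_len(nrow(grid))),
                 reads = 1L)
}

# Run one simulated cell through projection and polarity scoring.
cell_polarity <- function(spec, seed, panel) {
  sim <- simulate_cell(spec, seed = seed)
  g <- build_graph(edge_list(sim))
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(g, which(comp$membership ==
                                               which.max(comp$csize)))
  proj <- project_a_graph(giant, panel = panel)
  polarity_scores(proj)
}
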