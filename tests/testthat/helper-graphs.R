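# Fixture builders and independent brute-force oracles used across tests.

# Named graph from an edge matrix of 0-indexed ids (classic-dataset style).
graph_from_pairs <- function(pairs, n = max(pairs) + 1L) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(pairs + 1L))
  igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n) - 1L))
}

triangle_pair <- function() {
  # two triangles {0,1,2} and {3,4,5} bridged by the edge 2-3
  graph_from_pairs(rbind(c(0, 1), c(0, 2), c(1, 2),
                         c(3, 4), c(3, 5), c(4, 5), c(2, 3)))
}

path_graph <- function(n) {
  graph_from_pairs(cbind(0:(n - 2L), 1:(n - 1L)))
}

# Connected Erdos-Renyi graph (resamples until connected).
random_connected_graph <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
  }
  igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n) - 1L))
}

# --- oracles (kept independent of the package's computation paths) ---------

# Newman-Girvan modularity by the explicit double sum over all node pairs.
brute_modularity <- function(g, m) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  k <- rowSums(A)
  two_m <- sum(k)
  m <- as.integer(factor(as.vector(m)))
  same <- outer(m, m, "==")
  sum((A - outer(k, k) / two_m) * same) / two_m
}

# Danon-style NMI from the explicit contingency table.
brute_nmi <- function(a, b) {
  tab <- table(as.vector(a), as.vector(b))
  n <- sum(tab)
  I <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (tab[i, j] > 0)
      I <- I + tab[i, j] / n *
        log(tab[i, j] * n / (sum(tab[i, ]) * sum(tab[, j])))
  }
  H <- function(p) { p <- p[p > 0] / sum(p); -sum(p * log(p)) }
  Ha <- H(rowSums(tab)); Hb <- H(colSums(tab))
  if (Ha + Hb == 0) return(1)
  2 * I / (Ha + Hb)
}

# Per-node triangle counts by enumerating all node triples.
brute_triangles <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  out <- integer(n)
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      if (A[i, j] && A[j, k] && A[i, k]) {
        out[i] <- out[i] + 1L; out[j] <- out[j] + 1L; out[k] <- out[k] + 1L
      }
    }
  }
  out
}

expect_valid_graph <- function(g) {
  expect_true(igraph::is_igraph(g))
  expect_false(igraph::is_directed(g))
  expect_false(igraph::any_loop(g))
  expect_false(igraph::any_multiple(g))
  # adjacency symmetric and consistent with 2m
  expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
}
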