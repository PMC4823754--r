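# Evaluation metrics: Newman-Girvan modularity, normalized mutual
# information, rich-club connectivity.

# Align two membership vectors (by names when both are named).
align_memberships <- function(a, b) {
  if (length(a) != length(b))
    stop("memberships cover different node sets", call. = FALSE)
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("memberships cover different node sets", call. = FALSE)
    b <- b[names(a)]
  }
  list(a = as.integer(factor(as.vector(a))),
       b = as.integer(factor(as.vector(b))))
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * delta(c_i, c_j)`: the
#' within-community edge mass compared to a degree-preserving random
#' expectation. Lies in `[-1, 1)`; the all-in-one-community partition scores
#' exactly 0.
#'
#' @param g A simple undirected igraph object with at least one edge.
#' @param m Membership vector over the nodes of `g` (aligned by names when
#'   named, else by vertex order).
#' @return The modularity, a single number.
#' @examples
#' k <- classic_fixture("karate")
#' modularity_q(k$graph, k$membership)  # ~0.37
#' @export
modularity_q <- function(g, m) {
  assert_graph(g)
  if (igraph::ecount(g) == 0L) stop("edgeless graph", call. = FALSE)
  m <- check_node_vector(m, g, "m")
  if (!is.null(names(m))) {
    nm <- node_names(g)
    if (!setequal(names(m), nm))
      stop("membership names do not match graph nodes", call. = FALSE)
    m <- m[nm]
  }
  igraph::modularity(g, as.integer(factor(as.vector(m))))
}

#' Normalized mutual information between two partitions
#'
#' The community-detection standard `2 I(A, B) / (H(A) + H(B))`: 1 when the
#' partitions are identical up to relabeling, 0 when the label contingency
#' table factorizes (independent partitions). Symmetric and invariant under
#' label permutation. When both partitions are a single cluster they are
#' identical, so the degenerate `0/0` resolves to 1.
#'
#' @param a,b Membership vectors over the same node set (aligned by names
#'   when both are named).
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  al <- align_memberships(a, b)
  tab <- table(al$a, al$b)
  n <- sum(tab)
  pij <- tab / n
  pa <- rowSums(pij)
  pb <- colSums(pij)
  Ha <- -sum(pa * log(pa))
  Hb <- -sum(pb * log(pb))
  if (Ha + Hb == 0) return(1)   # both single-cluster: identical partitions
  nz <- pij > 0
  I <- sum(pij[nz] * log(pij[nz] / outer(pa, pb)[nz]))
  2 * I / (Ha + Hb)
}

#' Rich-club connectivity
#'
#' The fraction of possible edges realized among the `k` highest-degree
#' nodes (degree ties broken by lower node index), reported together with
#' the normalized rank position `r = k / n`. Densely interconnected hubs --
#' phi above roughly 0.5 -- signal that community centers are directly
#' linked, the regime in which center-based detection degrades; the default
#' `k` is logarithmic in the node count, so the club under examination stays
#' small.
#'
#' @param g A simple undirected igraph object.
#' @param k Number of top-degree nodes to examine, `2 <= k <= n`; default
#'   `max(2, round(log(n)))`.
#' @return A list with `k`, `r`, `phi`, and the `nodes` (labels) examined.
#' @examples
#' k <- classic_fixture("karate")
#' rich_club(k$graph, k = 2)$phi  # 0: the two faction leaders are not adjacent
#' @export
rich_club <- function(g, k = NULL) {
  assert_graph(g)
  n <- igraph::vcount(g)
  k <- as.integer(k %||% max(2, round(log(n))))
  if (length(k) != 1L || is.na(k) || k < 2L || k > n)
    stop("`k` must be in [2, ", n, "]", call. = FALSE)
  deg <- igraph::degree(g)
  top <- order(-deg, seq_len(n))[seq_len(k)]
  sub <- igraph::induced_subgraph(g, top)
  list(k = k, r = k / n,
       phi = igraph::ecount(sub) / choose(k, 2),
       nodes = node_names(g)[top])
}
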