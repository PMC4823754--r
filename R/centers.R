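# Community centrality and center election.

#' Community centrality
#'
#' Combines the density score and the reach distance into a single center
#' likelihood: `gamma_i = (eta_i / max(eta)) * (psi_i / cap)`. Both factors
#' are scaled to `[0, 1]` (density by its maximum, reach distance by the
#' search cap), so gamma is 1 exactly for a global density maximum and most
#' nodes score near zero -- the landscape in which a short sorted prefix of
#' gamma separates the centers.
#'
#' @param eta Density scores from [density_score()].
#' @param psi Reach distances from [eta_reach_distance()].
#' @param cap Search cap used for `psi`; defaults to `attr(psi, "cap")`.
#' @return Numeric vector of gamma values in `[0, 1]`, named like `eta`.
#' @export
community_centrality <- function(eta, psi, cap = attr(psi, "cap")) {
  if (length(eta) != length(psi))
    stop("`eta` and `psi` must have equal length", call. = FALSE)
  if (is.null(cap)) stop("`cap` missing and not recorded on `psi`", call. = FALSE)
  emax <- max(eta)
  if (emax <= 0)
    stop("all density scores are zero (edgeless graph?)", call. = FALSE)
  gamma <- (as.numeric(eta) / emax) * (as.numeric(psi) / cap)
  stats::setNames(gamma, names(eta) %||% names(psi))
}

#' Elect the top-C community centers
#'
#' The `C` nodes with the largest centrality, ties broken by lower node
#' index. The result for `C` is always a prefix of the result for `C + 1`.
#'
#' @param gamma Centrality values from [community_centrality()].
#' @param C Number of centers, `1 <= C <= length(gamma)`.
#' @return Integer vector of `C` node indices in descending-gamma order,
#'   named by node label when `gamma` is named.
#' @export
select_centers <- function(gamma, C) {
  C <- as.integer(C)
  if (length(C) != 1L || is.na(C) || C < 1L || C > length(gamma))
    stop("`C` must be in [1, ", length(gamma), "]", call. = FALSE)
  ord <- order(-gamma, seq_along(gamma))
  centers <- ord[seq_len(C)]
  stats::setNames(centers, names(gamma)[centers])
}

# Guarantee every connected component at least one center: components the
# top-C election missed are seeded with their own max-centrality node.
# No-op on connected graphs.
complete_centers <- function(g, centers, gamma) {
  comp <- igraph::components(g)$membership
  missed <- setdiff(unique(comp), unique(comp[centers]))
  for (cc in missed) {
    idx <- which(comp == cc)
    extra <- idx[which.max(gamma[idx])]
    centers <- c(centers, stats::setNames(extra, node_names(g)[extra]))
  }
  centers
}

#' Choose the number of communities by a modularity scan
#'
#' Runs the full center-election-plus-propagation pipeline for each
#' candidate `C` and keeps the partition with the largest modularity (ties
#' go to the smallest `C`). This is the default way of fixing `C` when it is
#' unknown; [turning_point()] is a faster alternative when the sorted
#' centrality curve has an obvious break.
#'
#' @param g A simple undirected connected igraph object.
#' @param gamma Centrality values from [community_centrality()].
#' @param C_range Candidate counts; default `2:min(20, ceiling(sqrt(n)))`.
#' @param min_labeled_neighbors Propagation threshold, see
#'   [propagate_labels()].
#' @return A list with the chosen `C`, `centers`, `membership`, `Q`, and a
#'   `scan` data frame of the modularity obtained at every candidate `C`.
#' @export
select_c_by_modularity <- function(g, gamma, C_range = NULL,
                                   min_labeled_neighbors = 1L) {
  assert_graph(g)
  gamma <- check_node_vector(gamma, g, "gamma")
  n <- igraph::vcount(g)
  C_range <- C_range %||% seq(2L, max(2L, min(20L, ceiling(sqrt(n)))))
  C_range <- as.integer(C_range)
  if (!length(C_range) || any(C_range < 1L | C_range > n))
    stop("`C_range` must be non-empty and within [1, ", n, "]", call. = FALSE)
  best <- NULL
  scan <- data.frame(C = C_range, Q = NA_real_)
  for (k in seq_along(C_range)) {
    C <- C_range[k]
    centers <- complete_centers(g, select_centers(gamma, C), gamma)
    part <- propagate_labels(g, centers, gamma,
                             min_labeled_neighbors = min_labeled_neighbors)
    Q <- modularity_q(g, part$membership)
    scan$Q[k] <- Q
    if (is.null(best) || Q > best$Q + 1e-12)
      best <- list(C = length(centers), centers = centers,
                   membership = part$membership, trace = part$trace, Q = Q)
  }
  best$scan <- scan
  best
}

#' Estimate the number of centers from the sorted centrality curve
#'
#' Sorts the positive centrality values in descending order and returns the
#' prefix length `k` (within `2..window`) that maximizes the drop ratio
#' `gamma_(k) / gamma_(k+1)`, provided that maximal drop is *obvious*
#' (`min_ratio`, default 2.2). A weak or absent break returns `NA` so
#' callers can fall back to [select_c_by_modularity()] -- a barely-sloping
#' curve carries no reliable center count, and on such graphs the scan is
#' the dependable choice.
#'
#' The threshold sits deliberately above 2: with the default reach cap of
#' 3, two nodes of similar density on either side of a psi step from 2 to
#' 1 produce a drop ratio approaching 2 purely through distance
#' quantization, with no community structure behind it. A break must beat
#' that artifact bound with some headroom before it is trusted. The
#' drop-ratio rule is one defensible formalization of an otherwise visual
#' criterion. Prefix lengths start at 2 because a single community is
#' never elected automatically; request `C = 1` explicitly for that.
#'
#' @param gamma Centrality values from [community_centrality()].
#' @param window Number of leading positions to search (default 20).
#' @param min_ratio Minimum drop ratio for a break to count as obvious
#'   (default 2.2).
#' @return The estimated count (`>= 2`), or `NA_integer_` when no obvious
#'   turning point exists.
#' @export
turning_point <- function(gamma, window = 20L, min_ratio = 2.2) {
  pos <- sort(gamma[gamma > 0], decreasing = TRUE)
  if (length(pos) < 3L)
    stop("need at least 3 nodes with positive centrality", call. = FALSE)
  kmax <- min(as.integer(window), length(pos) - 1L)
  if (kmax < 2L) return(NA_integer_)
  ks <- 2:kmax
  ratios <- pos[ks] / pos[ks + 1L]
  if (max(ratios) < min_ratio) return(NA_integer_)  # no obvious break
  ks[which.max(ratios)]
}
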