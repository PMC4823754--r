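# Greedy majority-vote label propagation from the elected centers.

#' Propagate center labels through the graph
#'
#' Each center carries its own label (1 for the top-centrality center, 2
#' for the next, ...). Remaining nodes are labeled one at a time, most
#' confident node first. A node with at least `min_labeled_neighbors`
#' labeled neighbours is a candidate; a candidate's vote counts as
#' *sufficiently informed* when a center sits among its labeled neighbours
#' (the vote is anchored to a center's direct authority) or when at least
#' half of its neighbours are labeled. Each iteration processes the
#' largest-centrality sufficiently-informed candidate (ties to the lower
#' node index); when none exists the largest-centrality candidate is
#' processed anyway, which guarantees progress on any graph whose every
#' component contains a center. The processed node adopts the label
#' occurring most frequently among its labeled neighbours; vote ties go to
#' the label whose labeled supporters have the greatest total centrality,
#' then to the smaller label id. All rules are total orders, so the
#' propagation is fully deterministic and the assignment trace is
#' reproducible.
#'
#' The informedness requirement is what keeps the diffusion from leaking
#' across community boundaries: without it, a node whose few labeled
#' neighbours all happen to lie across inter-community edges votes on that
#' misleading evidence while its own community is still unlabeled, and the
#' foreign label can cascade. Near a center the evidence is authoritative
#' and voting early is exactly right; away from the centers a node waits
#' until half its neighbourhood has spoken.
#'
#' @param g A simple undirected igraph object. Every connected component
#'   must contain at least one center, otherwise the stranded nodes are
#'   reported as an error.
#' @param centers Center node indices from [select_centers()].
#' @param gamma Centrality values from [community_centrality()].
#' @param min_labeled_neighbors Minimum labeled neighbours a node needs
#'   before it may vote (default 1). Larger values postpone
#'   low-information votes but can strand nodes; stranded nodes are an
#'   error.
#' @return A list with `membership` (named integer vector of community
#'   labels in `1..C`), `centers`, and `trace`, a data frame of the
#'   `(step, node, label)` assignment events in order.
#' @export
propagate_labels <- function(g, centers, gamma, min_labeled_neighbors = 1L) {
  assert_graph(g)
  gamma <- check_node_vector(gamma, g, "gamma")
  n <- igraph::vcount(g)
  centers <- as.integer(centers)
  if (!length(centers) || anyDuplicated(centers) ||
      any(centers < 1L | centers > n))
    stop("`centers` must be distinct node indices in [1, ", n, "]",
         call. = FALSE)
  min_labeled_neighbors <- max(1L, as.integer(min_labeled_neighbors))
  adj <- adj_list_int(g)
  deg <- lengths(adj)
  C <- length(centers)
  label <- integer(n)              # 0 = unlabeled
  label[centers] <- seq_len(C)
  nlab <- integer(n)               # labeled-neighbour counts
  for (c in centers) nlab[adj[[c]]] <- nlab[adj[[c]]] + 1L
  is_center <- logical(n)
  is_center[centers] <- TRUE
  near_center <- logical(n)        # has a center among its neighbours
  for (c in centers) near_center[adj[[c]]] <- TRUE
  todo <- n - C
  trace_node <- integer(todo)
  trace_label <- integer(todo)
  for (step in seq_len(todo)) {
    cand <- which(label == 0L & nlab >= min_labeled_neighbors)
    if (!length(cand)) {
      stranded <- node_names(g)[label == 0L]
      stop("propagation stranded ", length(stranded), " node(s): ",
           paste(head(stranded, 10L), collapse = ", "),
           if (length(stranded) > 10L) ", ..." else "",
           " (component without a center?)", call. = FALSE)
    }
    informed <- cand[near_center[cand] | 2L * nlab[cand] >= deg[cand]]
    pool <- if (length(informed)) informed else cand
    v <- pool[which.max(gamma[pool])]   # which.max: first max = lowest index
    nb <- adj[[v]]
    nb <- nb[label[nb] > 0L]
    votes <- tabulate(label[nb], nbins = C)
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      support <- vapply(top, function(l) sum(gamma[nb[label[nb] == l]]),
                        numeric(1))
      top <- top[support == max(support)]
    }
    lab <- min(top)
    label[v] <- lab
    nlab[adj[[v]]] <- nlab[adj[[v]]] + 1L
    trace_node[step] <- v
    trace_label[step] <- lab
  }
  nm <- node_names(g)
  list(membership = stats::setNames(label, nm),
       centers = stats::setNames(centers, nm[centers]),
       trace = data.frame(step = seq_len(todo), node = nm[trace_node],
                          label = trace_label))
}
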