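# The three-stage detection pipeline: density -> centrality -> propagation.

#' Detect communities by electing centers and propagating their labels
#'
#' Runs the full pipeline: per-node density scores ([density_score()]),
#' capped reach distances ([eta_reach_distance()]), community centrality
#' ([community_centrality()]), center election, and greedy label
#' propagation ([propagate_labels()]). When the number of communities is
#' unknown (`C = "auto"`, the default) it is read off the sorted
#' centrality curve whenever that curve has an obvious turning point
#' ([turning_point()]), and otherwise chosen by a modularity scan
#' ([select_c_by_modularity()]); either route can be forced via `select`,
#' and a fixed `C` can be supplied.
#'
#' Before detection, the rich-club connectivity over a logarithmic number
#' of top-degree nodes is examined; when it exceeds 0.5 the likely
#' community centers are densely interconnected -- the regime where
#' center-based detection is known to blur community boundaries -- and a
#' warning is issued.
#'
#' Disconnected graphs: communities never span components, and both the
#' capped breadth-first search and the propagation are naturally
#' component-confined, so the pipeline runs unchanged on a disconnected
#' graph when `on_disconnected = "asis"` -- every component is guaranteed
#' at least one center (a component the top-C election missed is seeded
#' with its own highest-centrality node, and the reported `C` counts those
#' extra centers). `"largest"` restricts to the largest component instead,
#' and the default `"error"` refuses, which keeps accidental disconnection
#' visible in interactive use.
#'
#' @param g A simple undirected igraph object.
#' @param density Density variant, `"degree"` (default) or `"strong_tie"`.
#' @param cap Reach-distance search cut-off (default 3).
#' @param C `"auto"` (default) or a fixed number of communities.
#' @param select How to choose `C` when `"auto"`: `"auto"` (default;
#'   obvious turning point, else scan), `"turning_point"`, or
#'   `"modularity"`.
#' @param C_range Candidate counts for the scan; default
#'   `2:min(20, ceiling(sqrt(n)))`.
#' @param min_labeled_neighbors Propagation threshold, see
#'   [propagate_labels()].
#' @param rich_club_k Club size for the pre-screen; default
#'   `max(2, round(log(n)))`.
#' @param on_disconnected What to do with a disconnected input: `"error"`
#'   (default), `"largest"` (use the largest component), or `"asis"` (run
#'   on all components; see Details).
#' @return An object of class `centerfind_result`: a list with
#'   `membership` (named community labels), `centers` (named indices,
#'   descending centrality), `C`, `Q` (modularity of the final partition),
#'   `gamma`, `eta`, `psi`, `trace`, `rich_club` (the pre-screen report),
#'   `scan` (modularity per candidate `C`, when scanned), and `config`.
#' @examples
#' k <- classic_fixture("karate")
#' res <- detect_communities(k$graph)
#' res$C                      # 2
#' names(res$centers)         # "33" "0"
#' round(res$Q, 2)            # 0.37
#' @export
detect_communities <- function(g,
                               density = c("degree", "strong_tie"),
                               cap = 3L,
                               C = "auto",
                               select = c("auto", "turning_point",
                                          "modularity"),
                               C_range = NULL,
                               min_labeled_neighbors = 1L,
                               rich_club_k = NULL,
                               on_disconnected = c("error", "largest",
                                                   "asis")) {
  assert_graph(g)
  density <- match.arg(density)
  select <- match.arg(select)
  on_disconnected <- match.arg(on_disconnected)
  if (!identical(C, "auto")) {
    C <- as.integer(C)
    if (is.na(C) || C < 1L)
      stop("`C` must be \"auto\" or a positive integer", call. = FALSE)
  }
  if (!igraph::is_connected(g)) {
    switch(on_disconnected,
           error = assert_connected(g),
           largest = { g <- largest_component(g) },
           asis = NULL)
  }
  n <- igraph::vcount(g)
  config <- list(density = density, cap = as.integer(cap), C = C,
                 select = select, C_range = C_range,
                 min_labeled_neighbors = as.integer(min_labeled_neighbors),
                 rich_club_k = rich_club_k,
                 on_disconnected = on_disconnected)

  rc <- rich_club(g, k = min(rich_club_k %||% max(2, round(log(n))), n))
  if (rc$phi > 0.5)
    warning(sprintf(paste0("rich-club connectivity %.2f over the top %d ",
                           "degrees exceeds 0.5: community centers appear ",
                           "densely interconnected and center-based ",
                           "detection may be unreliable here"),
                    rc$phi, rc$k), call. = FALSE)

  eta <- density_score(g, density)
  psi <- eta_reach_distance(g, eta, cap = cap)
  gamma <- community_centrality(eta, psi)

  run_fixed <- function(C) {
    centers <- complete_centers(g, select_centers(gamma, C), gamma)
    part <- propagate_labels(g, centers, gamma,
                             min_labeled_neighbors = min_labeled_neighbors)
    list(C = length(centers), centers = centers,
         membership = part$membership, trace = part$trace,
         Q = modularity_q(g, part$membership), scan = NULL)
  }

  if (identical(C, "auto")) {
    tp <- if (select %in% c("auto", "turning_point"))
      turning_point(gamma) else NA_integer_
    pick <- if (!is.na(tp)) {
      run_fixed(tp)
    } else {
      select_c_by_modularity(g, gamma, C_range = C_range,
                             min_labeled_neighbors = min_labeled_neighbors)
    }
  } else {
    pick <- run_fixed(C)
  }

  structure(list(membership = pick$membership, centers = pick$centers,
                 C = pick$C, Q = pick$Q,
                 gamma = gamma, eta = eta, psi = psi, trace = pick$trace,
                 rich_club = rc, scan = pick$scan, config = config,
                 n = n, m = igraph::ecount(g)),
            class = "centerfind_result")
}

#' @export
print.centerfind_result <- function(x, ...) {
  cat(sprintf("Center-based community detection (%d nodes, %d edges)\n",
              x$n, x$m))
  cat(sprintf("  density: %s, cap: %d\n", x$config$density, x$config$cap))
  cat(sprintf("  communities: %d (Q = %.4f)\n", x$C, x$Q))
  cat("  centers:", paste(names(x$centers), collapse = ", "), "\n")
  if (x$rich_club$phi > 0.5)
    cat(sprintf("  warning: rich-club phi = %.2f at k = %d\n",
                x$rich_club$phi, x$rich_club$k))
  invisible(x)
}
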