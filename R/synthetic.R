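# Benchmark generators with known ground truth.

# --- truncated power-law helpers -------------------------------------------

# Mean of a continuous power law with density ~ x^-t on [a, b].
pl_mean <- function(a, b, t) {
  if (abs(t - 1) < 1e-9) return((b - a) / log(b / a))
  if (abs(t - 2) < 1e-9) return(log(b / a) / (1 / a - 1 / b))
  ((b^(2 - t) - a^(2 - t)) / (2 - t)) / ((b^(1 - t) - a^(1 - t)) / (1 - t))
}

# Inverse-CDF sampler for the same distribution (t = 0 gives uniform).
pl_sample <- function(nsamp, a, b, t) {
  u <- runif(nsamp)
  if (abs(t - 1) < 1e-9) return(a * (b / a)^u)
  (a^(1 - t) + u * (b^(1 - t) - a^(1 - t)))^(1 / (1 - t))
}

# --- LFR-style benchmark ----------------------------------------------------

#' Parameter bundle for the LFR-style benchmark
#'
#' Collects and validates the generator parameters: node count `n`, target
#' average degree `avg_degree`, mixing parameter `mu` (the fraction of each
#' node's edges that leave its community), the negative exponents `t1`
#' (degree distribution) and `t2` (community-size distribution), community
#' size bounds `c_min`/`c_max`, and the overlap description (`n_overlap`
#' nodes carrying `m_overlap` memberships each). `t2 = 0` means community
#' sizes are drawn uniformly from `[c_min, c_max]`.
#'
#' @param n Number of nodes.
#' @param avg_degree Target mean degree.
#' @param mu Mixing parameter in `[0, 1]`.
#' @param t1,t2 Power-law exponents (used as negative) for degrees and
#'   community sizes.
#' @param c_min,c_max Community size bounds.
#' @param n_overlap,m_overlap Number of overlapping nodes and memberships
#'   per overlapping node (`m_overlap >= 2` when `n_overlap > 0`).
#' @param max_degree Upper truncation of the degree draw; default `n / 10`
#'   (at least one above the average degree), which keeps small benchmarks
#'   realizable.
#' @param seed Optional random seed stored with the parameters.
#' @return An object of class `lfr_params`.
#' @export
lfr_params <- function(n, avg_degree, mu, t1 = 2, t2 = 1, c_min, c_max,
                       n_overlap = 0L, m_overlap = 0L,
                       max_degree = NULL, seed = NULL) {
  stopifnot(n >= 2, avg_degree > 1, t1 >= 0, t2 >= 0)
  if (mu < 0 || mu > 1) stop("`mu` must be in [0, 1]", call. = FALSE)
  if (!(c_min <= c_max && c_max <= n))
    stop("need c_min <= c_max <= n", call. = FALSE)
  if (n_overlap > n) stop("`n_overlap` cannot exceed n", call. = FALSE)
  if (n_overlap > 0 && m_overlap < 2)
    stop("`m_overlap` must be >= 2 when overlapping nodes are requested",
         call. = FALSE)
  max_degree <- as.integer(max_degree %||%
                             min(n - 1, max(ceiling(n / 10),
                                            ceiling(avg_degree) + 1L)))
  if (max_degree < avg_degree)
    stop("`max_degree` below the target average degree", call. = FALSE)
  structure(list(n = as.integer(n), avg_degree = avg_degree, mu = mu,
                 t1 = t1, t2 = t2, c_min = as.integer(c_min),
                 c_max = as.integer(c_max), n_overlap = as.integer(n_overlap),
                 m_overlap = as.integer(m_overlap), max_degree = max_degree,
                 seed = seed),
            class = "lfr_params")
}

#' @export
print.lfr_params <- function(x, ...) {
  cat(sprintf(
    "LFR parameters: n=%d, <k>=%.3g, mu=%.2f, t1=%g, t2=%g, sizes [%d, %d]",
    x$n, x$avg_degree, x$mu, x$t1, x$t2, x$c_min, x$c_max))
  if (x$n_overlap > 0)
    cat(sprintf(", %d overlap nodes x %d memberships", x$n_overlap,
                x$m_overlap))
  cat("\n")
  invisible(x)
}

# Draw community sizes summing exactly to n.
sample_community_sizes <- function(n, t2, c_min, c_max, max_attempts = 200L) {
  if (c_min == c_max) {
    if (n %% c_min != 0L)
      stop("n is not divisible by the fixed community size ", c_min,
           call. = FALSE)
    return(rep.int(c_min, n %/% c_min))
  }
  for (attempt in seq_len(max_attempts)) {
    sizes <- integer(0)
    while (sum(sizes) < n) {
      s <- round(pl_sample(1L, c_min, c_max, t2))
      sizes <- c(sizes, min(max(s, c_min), c_max))
    }
    excess <- sum(sizes) - n
    if (excess > 0) {
      for (i in order(sizes, decreasing = TRUE)) {
        take <- min(excess, sizes[i] - c_min)
        sizes[i] <- sizes[i] - take
        excess <- excess - take
        if (excess == 0L) break
      }
    }
    if (excess == 0L) return(sizes)
  }
  stop("could not realize community sizes summing to n; ",
       "check c_min/c_max against n", call. = FALSE)
}

# Draw an integer degree sequence with mean ~ k_m from a truncated power law.
sample_degree_sequence <- function(n, k_m, t1, k_max) {
  if (k_m >= k_max) stop("average degree must be below max_degree",
                         call. = FALSE)
  if (pl_mean(1, k_max, t1) > k_m) {
    x_min <- 1
  } else {
    x_min <- uniroot(function(a) pl_mean(a, k_max, t1) - k_m,
                     lower = 1, upper = k_max - 1e-6, tol = 1e-9)$root
  }
  deg <- round(pl_sample(n, x_min, k_max, t1))
  pmin(pmax(deg, 1L), k_max)
}

# Pair up stubs subject to a validity predicate, repairing bad pairs by
# random partner swaps. Returns a 2-column matrix; irreparable pairs (after
# the pass budget) are dropped.
pair_stubs <- function(stubs, valid_pair, max_pass = 100L) {
  if (length(stubs) %% 2L == 1L) stubs <- stubs[-sample(length(stubs), 1L)]
  npair <- length(stubs) %/% 2L
  if (npair == 0L) return(cbind(integer(0), integer(0)))
  stubs <- sample(stubs)
  u <- stubs[seq_len(npair) * 2L - 1L]
  v <- stubs[seq_len(npair) * 2L]
  for (pass in seq_len(max_pass)) {
    key <- paste(pmin(u, v), pmax(u, v))
    bad <- which(u == v | duplicated(key) | !valid_pair(u, v))
    if (!length(bad)) break
    for (i in bad) {
      j <- sample.int(npair, 1L)
      tmp <- v[i]; v[i] <- v[j]; v[j] <- tmp
    }
  }
  key <- paste(pmin(u, v), pmax(u, v))
  bad <- u == v | duplicated(key) | !valid_pair(u, v)
  cbind(u[!bad], v[!bad])
}

#' Generate an LFR-style benchmark graph with planted communities
#'
#' Degrees are drawn from a truncated power law with exponent `t1` and mean
#' close to `avg_degree`; community sizes from a power law with exponent
#' `t2` within `[c_min, c_max]`. Each node devotes `round(mu * k)` of its
#' `k` edge stubs to inter-community links and the rest to its own
#' community, so at low `mu` low-degree nodes are purely internal, as in
#' the reference benchmark model; stubs are joined by random matching, with
#' self-loops,
#' parallel edges and misplaced inter/intra pairs repaired by stub swaps
#' (irreparable stubs are dropped; generation aborts if more than 10% of
#' stubs would be lost). Overlapping nodes, when requested, split their
#' internal stubs evenly across their memberships; only the ground truth is
#' multi-labeled.
#'
#' The generated graph is simple and undirected but not guaranteed to be
#' connected at low average degree; run detection on
#' [largest_component()] output.
#'
#' @param params An [lfr_params()] bundle.
#' @param seed Random seed (defaults to `params$seed`); identical
#'   parameters and seed reproduce the identical graph.
#' @return A list with `graph` (igraph, vertex names `"1"..."n"`),
#'   `membership` (named vector of primary community labels),
#'   `memberships` (list of label vectors; longer than 1 only for overlap
#'   nodes), `params`, and realized `stats` (mean degree, mixing fraction,
#'   dropped-stub fraction).
#' @examples
#' p <- lfr_params(n = 50, avg_degree = 3, mu = 0.1, t1 = 2, t2 = 1,
#'                 c_min = 25, c_max = 25)
#' b <- lfr_benchmark(p, seed = 1)
#' table(b$membership)
#' @export
lfr_benchmark <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "lfr_params"))
  with_seed(seed, {
    n <- params$n
    sizes <- sample_community_sizes(n, params$t2, params$c_min, params$c_max)
    C <- length(sizes)
    comm <- rep.int(seq_len(C), sizes)[sample.int(n)]
    deg <- sample_degree_sequence(n, params$avg_degree, params$t1,
                                  params$max_degree)
    k_ext <- as.integer(round(params$mu * deg))  # per-node allocation
    k_int <- deg - k_ext
    over <- k_int - (sizes[comm] - 1L)     # internal degree must fit community
    k_int <- k_int - pmax(over, 0L)
    k_ext <- deg - k_int

    memberships <- as.list(comm)
    if (params$n_overlap > 0L) {
      if (C < params$m_overlap)
        stop("fewer communities than memberships per overlapping node",
             call. = FALSE)
      ov <- sample.int(n, params$n_overlap)
      for (v in ov)
        memberships[[v]] <- c(comm[v], sample(setdiff(seq_len(C), comm[v]),
                                              params$m_overlap - 1L))
    }

    # Internal stub shares per (node, community): round-robin for overlap.
    int_stubs <- vector("list", C)
    for (v in seq_len(n)) {
      cs <- memberships[[v]]
      share <- k_int[v] %/% length(cs) + (seq_along(cs) <= k_int[v] %% length(cs))
      for (j in seq_along(cs)) {
        if (share[j] > 0L)
          int_stubs[[cs[j]]] <- c(int_stubs[[cs[j]]], rep.int(v, share[j]))
      }
    }

    edges <- lapply(int_stubs, function(stubs)
      pair_stubs(stubs, function(u, v) rep.int(TRUE, length(u))))
    internal <- do.call(rbind, edges)

    shares_comm <- function(u, v)    # inter-community stubs must not close
      !mapply(function(a, b) any(memberships[[a]] %in% memberships[[b]]),
              u, v)
    ext_stubs <- rep.int(seq_len(n), k_ext)
    external <- if (length(ext_stubs) >= 2L && C > 1L)
      pair_stubs(ext_stubs, shares_comm) else cbind(integer(0), integer(0))

    el <- rbind(internal, external)
    # cross-batch duplicates (an external pair duplicating an internal one)
    key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el <- el[!duplicated(key), , drop = FALSE]

    dropped <- 1 - 2 * nrow(el) / sum(deg)
    if (dropped > 0.10)
      stop(sprintf(paste0("parameters unsatisfiable: %.0f%% of stubs could ",
                          "not be placed"), 100 * dropped), call. = FALSE)

    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(el))
    g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
    g <- igraph::simplify(g)
    assert_graph(g)

    same <- mapply(function(a, b) any(memberships[[a]] %in% memberships[[b]]),
                   el[, 1], el[, 2])
    nm <- as.character(seq_len(n))
    list(graph = g,
         membership = stats::setNames(comm, nm),
         memberships = stats::setNames(memberships, nm),
         params = params,
         stats = list(mean_degree = 2 * nrow(el) / n,
                      mu_realized = mean(!same),
                      dropped_stub_fraction = max(0, dropped)))
  })
}

# --- planted partition ------------------------------------------------------

#' Generate a planted-partition (stochastic block) graph
#'
#' `C` near-equal blocks; each within-block pair is linked with probability
#' `p_in`, each between-block pair with probability `p_out`. A lightweight
#' generator for unit tests and parameter-recovery checks.
#'
#' @param n Number of nodes.
#' @param C Number of blocks.
#' @param p_in,p_out Edge probabilities, `0 <= p_out <= p_in <= 1`.
#' @param seed Optional random seed.
#' @return A list with `graph` (igraph) and `membership` (named block
#'   labels).
#' @export
planted_partition <- function(n, C, p_in, p_out, seed = NULL) {
  stopifnot(n >= 2, C >= 1, C <= n)
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1))
    stop("need 0 <= p_out <= p_in <= 1", call. = FALSE)
  with_seed(seed, {
    comm <- sort(rep_len(seq_len(C), n))
    ij <- t(utils::combn(n, 2L))
    p <- ifelse(comm[ij[, 1]] == comm[ij[, 2]], p_in, p_out)
    el <- ij[runif(nrow(ij)) < p, , drop = FALSE]
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(el))
    g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
    assert_graph(g)
    list(graph = g,
         membership = stats::setNames(comm, as.character(seq_len(n))))
  })
}

# --- bundled classics -------------------------------------------------------

#' Load a bundled classic network with ground truth
#'
#' Currently `"karate"`: Zachary's 34-node, 78-edge karate club network with
#' the two-faction ground truth (political alignment during the club
#' conflict; node labels are the customary 0-indexed ids, the instructor is
#' node 0 and the president node 33). Note that actor 8 sides with the
#' officers' faction here although he ultimately joined the instructor's
#' club -- the faction alignment is the ground truth commonly used to score
#' community detection.
#'
#' @param name Fixture name.
#' @return A list with `graph`, `membership` (named faction labels), and
#'   `name`.
#' @export
classic_fixture <- function(name = "karate") {
  if (!identical(name, "karate"))
    stop("unknown fixture: ", name, " (available: karate)", call. = FALSE)
  edge_file <- system.file("extdata", "karate.edgelist",
                           package = "centerfind", mustWork = TRUE)
  truth_file <- system.file("extdata", "karate_factions.tsv",
                            package = "centerfind", mustWork = TRUE)
  g <- read_edge_list(edge_file)
  # canonical presentation: vertex order = numeric node id order
  ids <- as.integer(node_names(g))
  perm <- integer(length(ids))
  perm[order(ids)] <- seq_along(ids)
  g <- igraph::permute(g, perm)
  list(graph = g, membership = read_membership(truth_file, graph = g),
       name = name)
}
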