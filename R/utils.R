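# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' disturb an enclosing simulation.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Adjacency as a list of integer vectors (1-based internal vertex indices).
adj_list_int <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
}

assert_graph <- function(g, arg = "g") {
  if (!igraph::is_igraph(g))
    stop(sprintf("`%s` must be an igraph object", arg), call. = FALSE)
  if (igraph::is_directed(g))
    stop(sprintf("`%s` must be undirected; see read_edge_list()/read_gml() ",
                 arg), call. = FALSE)
  if (igraph::any_loop(g) || igraph::any_multiple(g))
    stop(sprintf("`%s` must be a simple graph (no loops or parallel edges)",
                 arg), call. = FALSE)
  invisible(g)
}

assert_connected <- function(g, hint = TRUE) {
  if (!igraph::is_connected(g)) {
    msg <- "graph is disconnected"
    if (hint) msg <- paste0(msg, "; run largest_component() first or use ",
                            "auto_largest_component = TRUE")
    stop(msg, call. = FALSE)
  }
  invisible(g)
}

node_names <- function(g) {
  nm <- igraph::V(g)$name
  if (is.null(nm)) as.character(seq_len(igraph::vcount(g))) else nm
}

# Align a per-node vector argument with a graph, by names when available.
check_node_vector <- function(x, g, arg = "x") {
  n <- igraph::vcount(g)
  if (length(x) != n)
    stop(sprintf("`%s` has length %d but the graph has %d nodes",
                 arg, length(x), n), call. = FALSE)
  x
}
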