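# Graph and membership input/output.
#
# All readers normalise to the same internal representation: a simple,
# undirected igraph object whose vertex names preserve the original node
# labels (first-appearance order fixes the internal vertex indices, so
# repeated runs are reproducible).

normalize_graph <- function(g) {
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  for (attr in igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, attr)   # weights etc. are not used
  assert_graph(g)
  g
}

#' Read a whitespace-separated edge list
#'
#' Each non-comment line holds two whitespace-separated node labels. Lines
#' starting with `#` and blank lines are ignored. Directed input is
#' symmetrized; self-loops and parallel edges are dropped. Node labels are
#' arbitrary strings; internal vertex order follows first appearance.
#'
#' @param path Path to the edge-list file.
#' @param directed_input Whether the file lists directed arcs. The result is
#'   an undirected simple graph either way; the flag only documents intent.
#' @return A simple undirected igraph object with vertex names.
#' @examples
#' f <- tempfile()
#' writeLines(c("0 1", "1 2", "0 2"), f)
#' g <- read_edge_list(f)
#' igraph::vcount(g); igraph::ecount(g)
#' @export
read_edge_list <- function(path, directed_input = FALSE) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nbad <- lengths(toks) != 2L
  if (any(nbad)) {
    lineno <- which(keep)[which(nbad)[1L]]
    stop(sprintf("parse error at line %d of %s: expected 2 tokens, found %d",
                 lineno, path, lengths(toks)[which(nbad)[1L]]), call. = FALSE)
  }
  if (!length(toks)) stop("no edges found in ", path, call. = FALSE)
  from <- vapply(toks, `[[`, "", 1L)
  to <- vapply(toks, `[[`, "", 2L)
  labels <- unique(c(rbind(from, to)))  # first-appearance order
  g <- igraph::graph_from_edgelist(
    cbind(match(from, labels), match(to, labels)),
    directed = directed_input)
  g <- igraph::set_vertex_attr(g, "name", value = labels)
  normalize_graph(g)
}

#' Read a GML graph file
#'
#' Standard node/edge blocks; a `directed 1` flag is honoured by
#' symmetrizing. Edge weights, if present, are read and discarded (the
#' detection method is unweighted). Vertex names come from the GML `label`
#' attribute when present, else from `id`.
#'
#' @param path Path to the GML file.
#' @return A simple undirected igraph object with vertex names.
#' @export
read_gml <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  g <- tryCatch(igraph::read_graph(path, format = "gml"),
                error = function(e)
                  stop("malformed GML in ", path, ": ", conditionMessage(e),
                       call. = FALSE))
  nm <- igraph::vertex_attr(g, "label") %||% igraph::vertex_attr(g, "id")
  if (!is.null(nm)) g <- igraph::set_vertex_attr(g, "name",
                                                 value = as.character(nm))
  for (attr in setdiff(igraph::vertex_attr_names(g), "name"))
    g <- igraph::delete_vertex_attr(g, attr)
  normalize_graph(g)
}

#' Extract the largest connected component
#'
#' Returns the induced subgraph on the largest connected vertex set
#' (ties broken by lowest component id). Vertex names are preserved, so the
#' correspondence with original labels survives reindexing.
#'
#' @param g A simple undirected igraph object.
#' @return The induced subgraph, an igraph object.
#' @export
largest_component <- function(g) {
  assert_graph(g)
  if (igraph::vcount(g) == 0L) stop("empty graph", call. = FALSE)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  igraph::induced_subgraph(g, keep)
}

#' Read or write a community membership file
#'
#' The file format is two whitespace-separated columns per line: node label,
#' community label (tab-separated on write). `read_membership()` returns a
#' named character vector mapping node label to community label; when a
#' graph is supplied the node set is validated against it.
#'
#' @param path File path.
#' @param graph Optional igraph object to validate node labels against.
#' @return Named character vector: `names` are node labels, values community
#'   labels.
#' @export
read_membership <- function(path, graph = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  tab <- read.table(path, header = FALSE, colClasses = "character",
                    col.names = c("node", "community"))
  if (anyDuplicated(tab$node))
    stop("node listed twice in ", path, ": ",
         paste(unique(tab$node[duplicated(tab$node)]), collapse = ", "),
         call. = FALSE)
  m <- stats::setNames(tab$community, tab$node)
  if (!is.null(graph)) {
    nm <- node_names(graph)
    missing_nodes <- setdiff(names(m), nm)
    if (length(missing_nodes))
      stop("nodes absent from graph: ",
           paste(head(missing_nodes, 5L), collapse = ", "), call. = FALSE)
    uncovered <- setdiff(nm, names(m))
    if (length(uncovered))
      stop("graph nodes without a membership entry: ",
           paste(head(uncovered, 5L), collapse = ", "), call. = FALSE)
    m <- m[nm]  # graph vertex order
  }
  m
}

#' @param m Named vector as returned by [read_membership()] or found in a
#'   detection result.
#' @rdname read_membership
#' @export
write_membership <- function(m, path) {
  if (is.null(names(m))) stop("membership must be a named vector", call. = FALSE)
  write.table(data.frame(node = names(m), community = as.vector(m)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Number of communities in a membership vector
#' @param m Membership vector (any label type).
#' @return Integer count of distinct community labels.
#' @export
n_communities <- function(m) length(unique(as.vector(m)))
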