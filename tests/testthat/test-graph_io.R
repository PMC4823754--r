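test_that("edge lists parse, symmetrize and drop self-loops", {
  f <- withr::local_tempfile()
  writeLines(c("# a comment", "", "0 1", "1 2", "0 2"), f)
  g <- read_edge_list(f)
  expect_valid_graph(g)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)
  expect_equal(igraph::V(g)$name, c("0", "1", "2"))

  writeLines(c("a b", "b a", "a a"), f)
  g <- read_edge_list(f)
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)

  # symmetrization is idempotent: reloading an undirected file changes nothing
  f2 <- withr::local_tempfile()
  el <- igraph::as_edgelist(g)
  writeLines(paste(el[, 1], el[, 2]), f2)
  g2 <- read_edge_list(f2)
  expect_true(igraph::identical_graphs(
    igraph::permute(g2, match(igraph::V(g2)$name, igraph::V(g)$name)), g,
    attrs = FALSE))
})

test_that("malformed edge lists are rejected with the offending line", {
  f <- withr::local_tempfile()
  writeLines(c("0 1", "1 2 3"), f)
  expect_error(read_edge_list(f), "line 2")
  expect_error(read_edge_list(file.path(tempdir(), "no-such-file")),
               "cannot read")
})

test_that("GML files load with the same normalization contract", {
  f <- withr::local_tempfile(fileext = ".gml")
  writeLines(c("graph [", "  directed 1",
               "  node [ id 0 label \"a\" ]",
               "  node [ id 1 label \"b\" ]",
               "  node [ id 2 label \"c\" ]",
               "  edge [ source 0 target 1 weight 2.5 ]",
               "  edge [ source 1 target 0 ]",
               "  edge [ source 1 target 2 ]",
               "  edge [ source 0 target 2 ]",
               "]"), f)
  g <- read_gml(f)
  expect_valid_graph(g)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)     # K3: symmetrized, weights dropped
  expect_length(igraph::edge_attr_names(g), 0)
  writeLines("graph [ node [", f)
  expect_error(read_gml(f), "malformed")
})

test_that("largest_component extracts a connected reindexed subgraph", {
  k3 <- graph_from_pairs(rbind(c(0, 1), c(1, 2), c(0, 2)))
  expect_equal(igraph::vcount(largest_component(k3)), 3)
  gd <- graph_from_pairs(rbind(c(0, 1), c(1, 2), c(0, 2), c(3, 4)))
  lc <- largest_component(gd)
  expect_equal(igraph::vcount(lc), 3)
  expect_true(igraph::is_connected(lc))
  expect_setequal(igraph::V(lc)$name, c("0", "1", "2"))
})

test_that("membership files round-trip and validate against the graph", {
  f <- withr::local_tempfile()
  writeLines(c("0\tA", "1\tA", "2\tB"), f)
  m <- read_membership(f)
  expect_equal(n_communities(m), 2)
  expect_equal(m[["2"]], "B")

  f2 <- withr::local_tempfile()
  write_membership(m, f2)
  expect_equal(read_membership(f2), m)

  writeLines(c("0\tA", "0\tB"), f)
  expect_error(read_membership(f), "twice")

  g <- graph_from_pairs(rbind(c(0, 1), c(1, 2)))
  writeLines(c("0\tA", "1\tA", "9\tB"), f)
  expect_error(read_membership(f, graph = g), "absent")
  writeLines(c("0\tA", "1\tA"), f)
  expect_error(read_membership(f, graph = g), "without a membership")
})

test_that("loads always satisfy the graph invariants", {
  f <- withr::local_tempfile()
  set.seed(7)
  for (i in 1:5) {
    n <- sample(4:12, 1)
    el <- cbind(sample(n, 20, TRUE), sample(n, 20, TRUE)) - 1L
    writeLines(paste(el[, 1], el[, 2]), f)
    # self-loops in the file are tolerated and dropped
    g <- tryCatch(read_edge_list(f), error = function(e) NULL)
    if (!is.null(g)) expect_valid_graph(g)
  }
})
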