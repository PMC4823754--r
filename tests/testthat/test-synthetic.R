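test_that("parameter bundles validate their invariants", {
  expect_s3_class(lfr_params(50, 3, 0.1, 2, 1, 25, 25), "lfr_params")
  expect_error(lfr_params(50, 3, 1.5, 2, 1, 25, 25), "mu")
  expect_error(lfr_params(50, 3, 0.1, 2, 1, 30, 25), "c_min")
  expect_error(lfr_params(50, 3, 0.1, 2, 1, 25, 25, n_overlap = 5,
                          m_overlap = 1), "m_overlap")
  expect_error(lfr_params(50, 30, 0.1, 2, 1, 25, 25, max_degree = 10),
               "max_degree")
})

test_that("fixed community sizes yield the implied community count", {
  b <- lfr_benchmark(lfr_params(50, 3, 0.1, 2, 1, 25, 25), seed = 1)
  expect_equal(as.integer(table(b$membership)), c(25L, 25L))
  expect_valid_graph(b$graph)
  expect_error(lfr_benchmark(lfr_params(50, 3, 0.1, 2, 1, 23, 23), seed = 1),
               "divisible")
})

test_that("mu = 0 produces no inter-community edges", {
  b <- lfr_benchmark(lfr_params(60, 4, 0, 2, 1, 20, 20), seed = 3)
  el <- igraph::as_edgelist(b$graph)
  expect_equal(sum(b$membership[el[, 1]] != b$membership[el[, 2]]), 0)
})

test_that("realized degree and mixing track the requested parameters", {
  # tolerances frozen from a 20-seed calibration of this generator
  p <- lfr_params(1000, 20, 0.1, 2, 1, 100, 500)
  for (seed in c(2, 12, 22)) {
    b <- lfr_benchmark(p, seed = seed)
    expect_lt(abs(b$stats$mean_degree - 20) / 20, 0.15)
    expect_lt(abs(b$stats$mu_realized - 0.1), 0.03)
    expect_valid_graph(b$graph)
    sizes <- table(b$membership)
    expect_true(all(sizes >= 100 & sizes <= 500))
  }
})

test_that("identical parameters and seed reproduce the identical graph", {
  p <- lfr_params(200, 6, 0.2, 2, 1, 40, 80)
  b1 <- lfr_benchmark(p, seed = 9)
  b2 <- lfr_benchmark(p, seed = 9)
  expect_true(igraph::identical_graphs(b1$graph, b2$graph))
  expect_identical(b1$membership, b2$membership)
  b3 <- lfr_benchmark(p, seed = 10)
  expect_false(isTRUE(all.equal(igraph::as_edgelist(b1$graph),
                                igraph::as_edgelist(b3$graph))))
})

test_that("overlapping nodes carry exactly the requested memberships", {
  p <- lfr_params(50, 3, 0.1, 2, 1, 25, 25, n_overlap = 5, m_overlap = 2)
  b <- lfr_benchmark(p, seed = 4)
  n_multi <- sum(lengths(b$memberships) == 2)
  expect_equal(n_multi, 5)
  expect_true(all(lengths(b$memberships) %in% 1:2))
})

test_that("planted partitions match their binomial edge-count moments", {
  n <- 120; C <- 3; p_in <- 0.3; p_out <- 0.05
  b <- planted_partition(n, C, p_in, p_out, seed = 8)
  expect_valid_graph(b$graph)
  expect_equal(as.integer(table(b$membership)), rep(40L, 3))
  el <- igraph::as_edgelist(b$graph)
  within <- sum(b$membership[el[, 1]] == b$membership[el[, 2]])
  across <- nrow(el) - within
  n_within_pairs <- C * choose(40, 2)
  n_across_pairs <- choose(n, 2) - n_within_pairs
  expect_lt(abs(within - n_within_pairs * p_in),
            3 * sqrt(n_within_pairs * p_in * (1 - p_in)))
  expect_lt(abs(across - n_across_pairs * p_out),
            3 * sqrt(n_across_pairs * p_out * (1 - p_out)))
  # limit case: two disjoint cliques
  cl <- planted_partition(10, 2, 1, 0, seed = 1)
  expect_equal(igraph::count_components(cl$graph), 2)
  expect_equal(igraph::ecount(cl$graph), 2 * choose(5, 2))
  expect_error(planted_partition(10, 2, 0.2, 0.5, seed = 1), "p_out")
})

test_that("the bundled karate fixture matches the published network", {
  k <- classic_fixture("karate")
  expect_equal(igraph::vcount(k$graph), 34)
  expect_equal(igraph::ecount(k$graph), 78)
  expect_valid_graph(k$graph)
  expect_equal(n_communities(k$membership), 2)
  # the two faction leaders are on opposite sides
  expect_false(k$membership[["0"]] == k$membership[["33"]])
  expect_error(classic_fixture("dolphins"), "unknown")
})

test_that("low mixing makes planted communities recoverable end to end", {
  p <- lfr_params(100, 5, 0.05, 2, 1, 50, 50)
  v <- vapply(1:3, function(s) {
    b <- lfr_benchmark(p, seed = s)
    r <- detect_communities(b$graph, C = 2, on_disconnected = "asis")
    nmi(r$membership, b$membership)
  }, numeric(1))
  expect_gte(median(v), 0.95)
})
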