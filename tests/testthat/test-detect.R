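test_that("the karate pipeline recovers the faction split exactly", {
  k <- classic_fixture("karate")
  res <- detect_communities(k$graph)
  expect_equal(res$C, 2)
  expect_setequal(names(res$centers), c("0", "33"))
  expect_equal(nmi(res$membership, k$membership), 1)
  expect_equal(res$Q, 0.37, tolerance = 0.005)
})

test_that("detection results are complete, deterministic run reports", {
  k <- classic_fixture("karate")
  r1 <- detect_communities(k$graph)
  r2 <- detect_communities(k$graph)
  expect_identical(r1$membership, r2$membership)
  expect_identical(r1$trace, r2$trace)
  expect_named(r1$config,
               c("density", "cap", "C", "select", "C_range",
                 "min_labeled_neighbors", "rich_club_k", "on_disconnected"))
  expect_equal(nrow(r1$trace), 34 - r1$C)
  expect_s3_class(r1, "centerfind_result")
  expect_output(print(r1), "communities: 2")
})

test_that("the full pipeline splits the bridged triangles", {
  # the two centers are adjacent here, so the pre-screen rightly warns
  res <- suppressWarnings(detect_communities(triangle_pair()))
  expect_equal(res$C, 2)
  expect_equal(unname(res$membership), c(1, 1, 1, 2, 2, 2))
  expect_setequal(names(res$centers), c("2", "3"))
})

test_that("disconnected inputs follow the requested policy", {
  g <- graph_from_pairs(rbind(c(0, 1), c(1, 2), c(0, 2),
                              c(3, 4), c(4, 5), c(3, 5)))
  expect_error(detect_communities(g), "disconnected")
  lc <- suppressWarnings(detect_communities(g, on_disconnected = "largest",
                                            C = 1))
  expect_equal(length(lc$membership), 3)
  full <- suppressWarnings(detect_communities(g, on_disconnected = "asis",
                                              C = 2))
  expect_equal(length(full$membership), 6)
  expect_equal(n_communities(full$membership), 2)
  # every component received a center even when C understates them
  g3 <- graph_from_pairs(rbind(c(0, 1), c(1, 2), c(0, 2),
                               c(3, 4), c(4, 5), c(3, 5),
                               c(6, 7), c(7, 8), c(6, 8)))
  r3 <- suppressWarnings(detect_communities(g3, on_disconnected = "asis",
                                            C = 2))
  expect_equal(r3$C, 3)
  expect_equal(n_communities(r3$membership), 3)
})

test_that("a dense hub clique triggers the rich-club pre-screen warning", {
  # clique of hubs, each hub dangling a path: centers are interconnected
  pairs <- rbind(t(utils::combn(0:3, 2)),
                 cbind(0:3, 4:7), cbind(4:7, 8:11))
  g <- graph_from_pairs(pairs)
  expect_warning(detect_communities(g, C = 2, rich_club_k = 4), "rich-club")
  k <- classic_fixture("karate")
  expect_silent(detect_communities(k$graph))
})

test_that("forcing C and selection modes are honoured", {
  k <- classic_fixture("karate")
  r4 <- detect_communities(k$graph, C = 4)
  expect_equal(r4$C, 4)
  expect_equal(n_communities(r4$membership), 4)
  rs <- detect_communities(k$graph, select = "modularity")
  expect_equal(rs$C, 2)        # the scan lands on the faction split too
  expect_false(is.null(rs$scan))
  expect_equal(max(rs$scan$Q), rs$Q)
})

test_that("strong-tie density also splits karate around the two leaders", {
  k <- classic_fixture("karate")
  res <- detect_communities(k$graph, density = "strong_tie")
  expect_equal(res$C, 2)
  expect_setequal(names(res$centers), c("0", "33"))
  # triangle scores move one borderline member relative to the degree run,
  # giving the club-joined split (Q 0.358) rather than the faction split
  expect_gte(nmi(res$membership, k$membership), 0.8)
  expect_gte(res$Q, 0.35)
})
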