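# labeled-enumeration oracle: count isomorphism classes of simple
# graphs on n nodes by canonicalizing every labeled graph with the
# all-permutations certificate
labeled_class_count <- function(n, connected_only = FALSE) {
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  seen <- new.env(parent = emptyenv())
  for (mask in 0:(2^nrow(pairs) - 1)) {
    sel <- bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)) > 0
    edges <- pairs[sel, , drop = FALSE]
    if (connected_only) {
      g <- igraph::make_empty_graph(n, directed = FALSE)
      if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
      if (!igraph::is_connected(g)) next
    }
    cert <- snaresat:::canonical_graph_bruteforce(n, edges)
    assign(cert, TRUE, envir = seen)
  }
  length(ls(envir = seen))
}

test_that("simple-graph enumeration matches the labeled oracle", {
  expect_length(enumerate_simple_graphs(1), 1L)
  expect_length(enumerate_simple_graphs(3, connected_only = TRUE), 2L)
  expect_length(enumerate_simple_graphs(4), 11L)
  for (n in 2:5)
    expect_length(enumerate_simple_graphs(n), labeled_class_count(n))
  expect_length(enumerate_simple_graphs(4, connected_only = TRUE),
                labeled_class_count(4, connected_only = TRUE))
  expect_error(enumerate_simple_graphs(10), "1 <= n <= 9")
})

test_that("BLISS certificates define the same equivalence as the all-permutations oracle", {
  # the two canonical forms differ as strings (different canonical
  # orderings) but must induce the same isomorphism relation
  set.seed(21)
  rand_edges <- function(n) {
    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    pairs[sample(c(TRUE, FALSE), nrow(pairs), replace = TRUE), , drop = FALSE]
  }
  for (rep in 1:40) {
    n <- sample(2:5, 1)
    e1 <- rand_edges(n); e2 <- rand_edges(n)
    fast_eq <- canonical_graph(n, e1)$certificate ==
      canonical_graph(n, e2)$certificate
    slow_eq <- snaresat:::canonical_graph_bruteforce(n, e1) ==
      snaresat:::canonical_graph_bruteforce(n, e2)
    expect_equal(fast_eq, slow_eq)
    # certificate invariance under relabeling
    perm <- sample(n)
    cg2 <- canonical_graph(n, cbind(perm[e1[, 1]], perm[e1[, 2]]))
    expect_equal(canonical_graph(n, e1)$certificate, cg2$certificate)
  }
})

test_that("no duplicate certificates; every labeled graph is covered", {
  graphs <- enumerate_simple_graphs(5)
  certs <- vapply(graphs, `[[`, "", "certificate")
  expect_equal(anyDuplicated(certs), 0L)
  expect_equal(certs, sort(certs))   # deterministic lexicographic order
  set.seed(31)
  for (rep in 1:20) {
    pairs <- which(upper.tri(matrix(TRUE, 5, 5)), arr.ind = TRUE)
    sel <- sample(c(TRUE, FALSE), nrow(pairs), replace = TRUE)
    cg <- canonical_graph(5, pairs[sel, , drop = FALSE])
    expect_true(cg$certificate %in% certs)
  }
})

test_that("the 3-edge-connected census counts exact connectivity", {
  expect_equal(count_k_edge_connected(4, 3), 1L)   # K4 only
  expect_equal(count_k_edge_connected(5, 3), 2L)   # K5-e and K5-2e; K5 is 4-connected
  expect_equal(count_k_edge_connected(3, 3), 0L)
  expect_equal(count_k_edge_connected(5, 3, at_least = TRUE), 3L)
  tab <- table_three_connected(5)
  expect_equal(tab$count, c(0L, 0L, 0L, 1L, 2L))
})

test_that("directed multigraph topology enumeration", {
  b <- search_bounds(2, 2, strongly_connected_only = TRUE)
  expect_length(enumerate_topologies(b), 3L)   # (1,1), (1,2), (2,2)
  b$strongly_connected_only <- FALSE
  all2 <- enumerate_topologies(b)
  expect_length(Filter(function(tp) sum(tp$mult) > 0, all2), 5L)
  b1 <- search_bounds(1, 2)
  expect_length(Filter(function(tp) sum(tp$mult) > 0,
                       enumerate_topologies(b1)), 0L)
  # certificates: equal iff isomorphic (igraph oracle on random pairs)
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(2:4, 1)
    m1 <- matrix(sample(0:2, n * n, replace = TRUE), n, n); diag(m1) <- 0L
    perm <- sample(n)
    m2 <- m1[perm, perm]    # isomorphic copy
    expect_equal(snaresat:::.topo_canon_cpp(m1), snaresat:::.topo_canon_cpp(m2))
    m3 <- m1
    off <- which(row(m3) != col(m3))
    m3[off[1]] <- (m3[off[1]] + 1L) %% 3L
    g1 <- igraph::graph_from_adjacency_matrix(m1, mode = "directed",
                                              weighted = TRUE)
    g3 <- igraph::graph_from_adjacency_matrix(m3, mode = "directed",
                                              weighted = TRUE)
    iso <- igraph::isomorphic(g1, g3, method = "vf2",
                              edge.color1 = igraph::E(g1)$weight,
                              edge.color2 = igraph::E(g3)$weight)
    expect_equal(snaresat:::.topo_canon_cpp(m1) == snaresat:::.topo_canon_cpp(m3),
                 iso)
  }
})
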