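umg <- function(mult) underlying_multigraph(mult)

test_that("edge connectivity on canonical examples", {
  # note: underlying_multigraph() takes DIRECTED multiplicities, so
  # simple undirected graphs enter as their upper triangle
  k4 <- (matrix(1L, 4, 4) - diag(1L, 4)) * upper.tri(diag(4))
  expect_equal(edge_connectivity(umg(k4)), 3)
  two4 <- matrix(c(0L, 2L, 2L, 0L), 2, 2)   # 2 nodes, multiplicity 4 total
  expect_equal(edge_connectivity(umg(two4)), 4)
  c5 <- matrix(0L, 5, 5)
  for (i in 1:5) c5[i, i %% 5 + 1] <- 1L
  expect_equal(edge_connectivity(umg(c5)), 2)
  disc <- matrix(0L, 4, 4); disc[1, 2] <- 1L; disc[3, 4] <- 1L
  expect_equal(edge_connectivity(umg(disc)), 0)
  expect_equal(edge_connectivity(umg(matrix(0L, 1, 1))), Inf)
  expect_error(edge_connectivity(umg(matrix(0L, 0, 0))), "empty")
})

test_that("subset enumeration and max-flow methods agree", {
  # enumerated simple graphs on up to 6 nodes
  for (n in 2:6) {
    for (g in enumerate_simple_graphs(n)) {
      A <- matrix(0L, n, n)
      if (nrow(g$edges)) { A[g$edges] <- 1L; A <- A + t(A) }
      gg <- umg(matrix(0L, n, n) + A * upper.tri(A))
      expect_equal(edge_connectivity(gg, method = "subset"),
                   edge_connectivity(gg, method = "maxflow"))
    }
  }
  # random multigraphs
  set.seed(3)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    m <- matrix(sample(0:2, n * n, replace = TRUE), n, n)
    diag(m) <- 0L
    g <- umg(m)
    expect_equal(edge_connectivity(g, method = "subset"),
                 edge_connectivity(g, method = "maxflow"))
  }
})

test_that("edge connectivity is monotone and degree-bounded", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    m <- matrix(sample(0:1, n * n, replace = TRUE), n, n)
    diag(m) <- 0L
    g <- umg(m)
    lam <- edge_connectivity(g)
    expect_lte(lam, min(rowSums(g$mult)))
    # adding an edge never decreases connectivity
    free <- which(m == 0L & row(m) != col(m))
    if (length(free)) {
      m2 <- m; m2[free[1]] <- 1L
      expect_gte(edge_connectivity(umg(m2)), lam)
    }
  }
})

test_that("strong connectivity examples and the 2-connected floor", {
  cyc2 <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  expect_true(is_strongly_connected(cyc2))
  one <- matrix(c(0L, 1L, 0L, 0L), 2, 2, byrow = TRUE)
  expect_false(is_strongly_connected(one))
  # strongly connected (n >= 2) implies underlying connectivity >= 2
  set.seed(9)
  for (rep in 1:40) {
    n <- sample(2:5, 1)
    m <- matrix(sample(0:2, n * n, replace = TRUE, prob = c(.6, .3, .1)), n, n)
    diag(m) <- 0L
    if (is_strongly_connected(m))
      expect_gte(edge_connectivity(umg(m)), 2)
  }
})

test_that("connectivity_class thresholds", {
  k5 <- (matrix(1L, 5, 5) - diag(1L, 5)) * upper.tri(diag(5))
  k4 <- (matrix(1L, 4, 4) - diag(1L, 4)) * upper.tri(diag(4))
  c5 <- matrix(0L, 5, 5); for (i in 1:5) c5[i, i %% 5 + 1] <- 1L
  expect_equal(connectivity_class(umg(k5), 4), "at_least_k")
  expect_equal(connectivity_class(umg(k4), 4), "between_k_minus_1_and_k")
  expect_equal(connectivity_class(umg(c5), 4), "below_k_minus_1")
})
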