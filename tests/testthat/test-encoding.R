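test_that("unregulated traffic admits no network at all", {
  b <- search_bounds(2, 2, strongly_connected_only = TRUE)
  enc <- encode_feasibility(b, regime_row(6), nodes = 2)
  expect_equal(solve_cnf(enc$cnf)$status, "UNSAT")
})

test_that("two-compartment 3-connected network exists under vesicle regulation", {
  b <- search_bounds(2, 6, strongly_connected_only = TRUE,
                     connectivity = list(type = "exact", k = 3L))
  enc <- encode_feasibility(b, regime_row(2), nodes = 2)
  v <- solve_cnf(enc$cnf)
  expect_equal(v$status, "SAT")
  inst <- decode_instance(v, enc)
  expect_true(validate_instance(inst)$pass)
  expect_equal(edge_connectivity(underlying_multigraph(inst$network)), 3)
  expect_error(decode_instance(solve_cnf(encode_feasibility(
    b, regime_row(6), nodes = 2)$cnf), enc), "UNSAT")
})

test_that("a single antiparallel edge pair is infeasible under every regime", {
  anti <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  for (row in 1:6) for (M in c(2, 4))
    expect_equal(solve_fixed(anti, regime_row(row), M)$status, "UNSAT")
})

test_that("fixed-topology round trip through the bundled fixture", {
  inst <- build_fixture("row2_two_compartment")
  mult <- matrix(0L, 2, 2)
  for (i in seq_along(inst$network$edge_src)) {
    u <- match(inst$network$edge_src[i], inst$network$node_ids)
    v <- match(inst$network$edge_tgt[i], inst$network$node_ids)
    mult[u, v] <- mult[u, v] + 1L
  }
  v <- solve_fixed(mult, regime_row(2), 6)
  expect_equal(v$status, "SAT")
  enc <- encode_feasibility(search_bounds(2, 6), regime_row(2),
                            fixed_topology = mult)
  inst2 <- decode_instance(solve_cnf(enc$cnf), enc)
  expect_true(validate_instance(inst2)$pass)
  # same topology up to isomorphism
  mult2 <- matrix(0L, 2, 2)
  for (i in seq_along(inst2$network$edge_src)) {
    u <- match(inst2$network$edge_src[i], inst2$network$node_ids)
    v2 <- match(inst2$network$edge_tgt[i], inst2$network$node_ids)
    mult2[u, v2] <- mult2[u, v2] + 1L
  }
  expect_equal(snaresat:::.topo_canon_cpp(mult), snaresat:::.topo_canon_cpp(mult2))
})

test_that("every decoded model passes validation and is strongly connected", {
  set.seed(77)
  cases <- list(list(row = 1, M = 4), list(row = 2, M = 6), list(row = 3, M = 6))
  for (cs in cases) {
    for (n in 2:3) {
      b <- search_bounds(n, cs$M, strongly_connected_only = TRUE)
      enc <- encode_feasibility(b, regime_row(cs$row), nodes = n)
      v <- solve_cnf(enc$cnf, seed = n)
      if (v$status != "SAT") next
      inst <- decode_instance(v, enc)
      expect_true(validate_instance(inst)$pass)
      expect_true(is_strongly_connected(inst$network))
      expect_gte(edge_connectivity(underlying_multigraph(inst$network)), 2)
    }
  }
})

test_that("decoded instances satisfy the requested connectivity class", {
  for (k in 3:4) {
    b <- search_bounds(2, 6, strongly_connected_only = TRUE,
                       connectivity = list(type = "exact", k = k))
    enc <- encode_feasibility(b, regime_row(1), nodes = 2)
    v <- solve_cnf(enc$cnf)
    expect_equal(v$status, "SAT")
    inst <- decode_instance(v, enc)
    expect_equal(edge_connectivity(underlying_multigraph(inst$network)), k)
  }
})

test_that("enlarging the molecule bound never flips SAT to UNSAT", {
  topos <- topologies_with_edges(2, strong = TRUE)
  for (tp in topos) for (row in c(1, 2)) {
    s4 <- solve_fixed(tp$mult, regime_row(row), 4)$status
    if (s4 == "SAT")
      expect_equal(solve_fixed(tp$mult, regime_row(row), 6)$status, "SAT")
  }
})
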