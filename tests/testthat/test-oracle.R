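test_that("oracle examples on canonical tiny topologies", {
  anti <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  cyc3 <- matrix(0L, 3, 3); cyc3[1, 2] <- cyc3[2, 3] <- cyc3[3, 1] <- 1L
  for (row in 1:6) {
    expect_false(brute_force_feasible(anti, regime_row(row), 2)$feasible)
    expect_false(brute_force_feasible(cyc3, regime_row(row), 2)$feasible)
  }
  # unregulated traffic: no topology is feasible
  for (tp in topologies_with_edges(2))
    expect_false(brute_force_feasible(tp$mult, regime_row(6), 4)$feasible)
})

test_that("oracle witnesses pass full validation", {
  found <- 0L
  for (tp in topologies_with_edges(2, strong = TRUE)) {
    for (row in 1:3) {
      r <- brute_force_feasible(tp$mult, regime_row(row), 4)
      if (r$feasible) {
        found <- found + 1L
        expect_true(validate_instance(r$witness)$pass)
      }
    }
  }
  expect_gt(found, 0L)
})

test_that("oracle refuses out-of-bounds problems and tiny budgets", {
  big <- matrix(0L, 4, 4); big[1, 2] <- big[2, 1] <- 1L
  expect_error(brute_force_feasible(big, regime_row(1), 2), "at most 3 nodes")
  anti <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  expect_error(brute_force_feasible(anti, regime_row(1), 6), "M <= 4")
  expect_error(brute_force_feasible(anti, regime_row(1), 4, budget = 10),
               "budget exceeded")
})

test_that("oracle and SAT engine agree on the full 2-node grid", {
  for (tp in topologies_with_edges(2)) {
    for (M in c(2, 4)) for (row in 1:6) {
      orc <- brute_force_feasible(tp$mult, regime_row(row), M)
      sat <- solve_fixed(tp$mult, regime_row(row), M)$status == "SAT"
      expect_equal(orc$feasible, sat,
                   info = sprintf("2-node grid row %d M %d", row, M))
    }
  }
})

test_that("minimum feasible connectivity: oracle and SAT engines agree", {
  b <- search_bounds(3, 4)
  for (row in c(1, 2)) {
    mo <- min_feasible_connectivity(regime_row(row), b, engine = "oracle")
    ms <- min_feasible_connectivity(regime_row(row), b, engine = "sat")
    expect_equal(mo, ms, info = paste("row", row))
    if (!is.null(mo)) expect_gte(mo, 2L)
  }
  expect_null(min_feasible_connectivity(regime_row(6), b, engine = "oracle"))
  expect_null(min_feasible_connectivity(regime_row(6), b, engine = "sat"))
})
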