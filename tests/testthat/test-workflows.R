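test_that("necessity verdicts reproduce the regime table at small bounds", {
  b <- search_bounds(3, 6)
  nv <- check_necessary(regime_row(2), 3, b)
  expect_true(nv$exists_at_k)
  expect_false(nv$exists_below_k)
  expect_true(nv$necessary)
  expect_true(validate_instance(nv$witness)$pass)
  nv6 <- check_necessary(regime_row(6), 3, b)
  expect_false(nv6$exists_at_k)
  expect_false(nv6$exists_below_k)
  expect_error(check_necessary(regime_row(2), 1, b), "k must be")
})

test_that("sufficiency holds for rows 1-2 at 8 molecules on 3 nodes", {
  b <- search_bounds(3, 8)
  for (row in c(1, 2)) {
    s <- check_sufficient(regime_row(row), 3, b)
    expect_true(s$all_feasible)
    expect_equal(length(s$counterexamples), 0L)
    expect_gt(s$checked_count, 60L)
  }
})

test_that("row-2 sufficiency at 3 nodes is a molecule-budget effect", {
  # at M = 6, 68 of the 70 strongly connected >=3-connected 3-node
  # topologies are infeasible under none/boolean; at M = 8 all are
  # feasible (see the methods vignette)
  s6 <- check_sufficient(regime_row(2), 3, search_bounds(3, 6))
  expect_equal(s6$checked_count, 70L)
  expect_equal(length(s6$counterexamples), 68L)
  # spot-check one counterexample against the oracle at M <= 4
  tp <- s6$counterexamples[[1]]
  expect_false(brute_force_feasible(tp$mult, regime_row(2), 4)$feasible)
})

test_that("sufficiency refutation stops early and reports counterexamples", {
  # row 3 needs 4-connectedness: some 3-connected topology is infeasible
  s <- check_sufficient(regime_row(3), 3, search_bounds(3, 6),
                        stop_at_first = TRUE)
  expect_false(s$all_feasible)
  expect_gte(length(s$counterexamples), 1L)
  tp <- s$counterexamples[[1]]
  expect_gte(tp$connectivity, 3)
  expect_true(tp$strong)
})

test_that("undirected-mode sufficiency is at most as strict", {
  b <- search_bounds(2, 6)
  sd <- check_sufficient(regime_row(3), 3, b)
  su <- check_sufficient(regime_row(3), 3, b, undirected_mode = TRUE)
  expect_true(su$all_feasible >= sd$all_feasible)
})

test_that("minimum connectivity workflow on the regime table", {
  b <- search_bounds(3, 6)
  expect_equal(min_feasible_connectivity(regime_row(2), b), 3L)
  expect_null(min_feasible_connectivity(regime_row(5), b))
})
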