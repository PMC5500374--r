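test_that("molecule universe partitions Q and R indices", {
  u <- molecule_universe(6)
  expect_equal(u$q_indices, 1:3)
  expect_equal(u$r_indices, 4:6)
  expect_error(molecule_universe(5), "even")
  expect_error(molecule_universe(0), "even|positive")
})

test_that("composition strings follow the Q-block/R-block convention", {
  # the worked example label [101 100] carries Q2, Q0 and R2
  comp <- comp_from_string("101 100", 6)
  expect_equal(which(comp == 1L), c(1L, 3L, 6L))   # Q0, Q2, R2 (1-based)
  expect_equal(comp_to_string(comp), "101 100")
  expect_equal(comp_to_string(comp, space = FALSE), "101100")
  # [111 110]: R0 absent, everything else present
  comp2 <- comp_from_string("111110", 6)
  expect_equal(which(comp2 == 0L), 4L)             # R0
  expect_equal(composition(c("Q2", "Q0", "R2"), molecule_universe(6)), comp)
  expect_error(comp_from_string("10110", 6), "6 binary digits")
})

test_that("transport network structural invariants are enforced", {
  uni <- u2
  comp <- c(1L, 1L)
  ok <- transport_network(uni, list(x = comp, y = comp),
                          list(vesicle_edge("x", "y", c(1L, 0L))))
  expect_s3_class(ok, "vt_network")
  expect_error(transport_network(uni, list(x = comp),
      list(vesicle_edge("x", "x", c(1L, 0L)))), "self edge")
  expect_error(transport_network(uni, list(x = comp, y = comp),
      list(vesicle_edge("x", "y", c(0L, 0L)))), "empty")
  expect_error(transport_network(uni, list(x = c(1L, 0L), y = comp),
      list(vesicle_edge("x", "y", c(1L, 1L)))), "absent from its source")
  expect_error(transport_network(uni, list(x = comp, y = comp),
      list(vesicle_edge("x", "y", c(1L, 0L)),
           vesicle_edge("x", "y", c(1L, 0L)))), "identical parallel")
  expect_error(transport_network(uni, list(x = comp, y = comp),
      list(vesicle_edge("x", "y", c(1L, 0L)),
           vesicle_edge("x", "y", c(0L, 1L)),
           vesicle_edge("x", "y", c(1L, 1L)))), "more than 2")
  expect_error(transport_network(uni, list(x = comp, y = comp),
      list(vesicle_edge("x", "z", c(1L, 0L)))), "unknown node")
})

test_that("pairing matrices only allow cross-class entries", {
  m <- matrix(0L, 4, 4)
  m[1, 3] <- 1L; m[4, 2] <- 1L
  expect_s3_class(pairing_matrix(m, u4), "vt_pairing")
  m[1, 2] <- 1L  # Q-Q entry
  expect_error(pairing_matrix(m, u4), "Q-R or R-Q")
})

test_that("the six regimes map to the standard table rows", {
  rows <- lapply(1:6, regime_row)
  keys <- vapply(rows, function(r)
    paste(r$compartment_rule, r$vesicle_rule), "")
  expect_equal(keys, c("boolean boolean", "none boolean",
                       "boolean snare_inhibition", "none snare_inhibition",
                       "boolean none", "none none"))
  expect_equal(anyDuplicated(keys), 0L)
  expect_error(regime_row(7), "1..6")
  expect_error(regulation_regime("snare_inhibition", "none"))
})
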