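test_that("active_molecules implements the three regulation rules", {
  uni <- u6
  pm0 <- pairing_matrix(matrix(0L, 6, 6), uni)
  comp <- composition(c("Q0", "R1"), uni)
  # no regulation: all present molecules are active
  expect_equal(active_molecules(comp, "vesicle",
                                regulation_regime("none", "none"), pm0), comp)
  # SNARE-SNARE inhibition: a co-present competent pair kills both
  m <- matrix(0L, 6, 6); m[1, 4] <- 1L   # Q0 (vesicle) - R0 (compartment)
  pm <- pairing_matrix(m, uni)
  comp2 <- composition(c("Q0", "R0", "Q1"), uni)
  act <- active_molecules(comp2, "vesicle",
                          regulation_regime("none", "snare_inhibition"), pm)
  expect_equal(act, composition("Q1", uni))
  # symmetric in the pair: either pairing orientation inhibits
  m2 <- matrix(0L, 6, 6); m2[4, 1] <- 1L  # R0 (vesicle) - Q0 (compartment)
  act2 <- active_molecules(comp2, "vesicle",
                           regulation_regime("none", "snare_inhibition"),
                           pairing_matrix(m2, uni))
  expect_equal(act2, composition("Q1", uni))
  # boolean regulation: explicit map, deactivating Q2 and R2 on [101 100]
  reg <- regulation_function(vesicle = c("101100" = "001000"))
  act3 <- active_molecules(comp_from_string("101100", 6), "vesicle",
                           regulation_regime("none", "boolean"), pm0, reg)
  expect_equal(act3, composition("Q0", uni))
  # unlisted compositions default to all-inactive; activity clipped to presence
  act4 <- active_molecules(comp2, "vesicle",
                           regulation_regime("none", "boolean"), pm0, reg)
  expect_equal(sum(act4), 0L)
  regbad <- regulation_function(vesicle = c("101100" = "010011"))
  act5 <- active_molecules(comp_from_string("101100", 6), "vesicle",
                           regulation_regime("none", "boolean"), pm0, regbad)
  expect_true(all(act5 <= comp_from_string("101100", 6)))
  # configuration errors
  expect_error(active_molecules(comp, "compartment",
      regulation_regime("boolean", "none"), pm0), "regulation function")
  expect_error(active_molecules(comp, "compartment",
      list(compartment_rule = "snare_inhibition", vesicle_rule = "none"),
      pm0), "compartment side")
})

test_that("activity is always a subset of presence across regimes", {
  uni <- u4
  set.seed(11)
  for (rep in 1:30) {
    m <- matrix(0L, 4, 4)
    m[1:2, 3:4] <- sample(0:1, 4, replace = TRUE)
    m[3:4, 1:2] <- sample(0:1, 4, replace = TRUE)
    pm <- pairing_matrix(m, uni)
    comp <- sample(0:1, 4, replace = TRUE)
    key <- comp_to_string(comp, space = FALSE)
    reg <- regulation_function(
      vesicle = setNames(comp_to_string(sample(0:1, 4, replace = TRUE),
                                        space = FALSE), key))
    for (vr in c("none", "boolean", "snare_inhibition")) {
      act <- active_molecules(comp, "vesicle",
                              regulation_regime("none", vr), pm, reg)
      expect_true(all(act <= comp))
      if (vr == "none") expect_equal(act, as.integer(comp))
    }
  }
})

test_that("fusion competence needs one active pair across membranes", {
  uni <- u6
  m <- matrix(0L, 6, 6); m[1, 4] <- 1L   # Q0 -> R0
  pm <- pairing_matrix(m, uni)
  expect_true(fusion_competent(composition("Q0", uni),
                               composition("R0", uni), pm))
  expect_false(fusion_competent(integer(6), composition("R0", uni), pm))
  expect_false(fusion_competent(composition("Q0", uni),
                                composition("R1", uni), pm))
})

test_that("identical vesicle labels must share a target", {
  uni <- u2
  comp <- c(1L, 1L)
  lab <- c(1L, 0L)
  net_ok <- transport_network(uni, list(x = comp, y = comp, z = comp),
    list(vesicle_edge("x", "y", lab), vesicle_edge("z", "y", lab)))
  expect_true(check_same_label_same_target(net_ok)$ok)
  net_bad <- transport_network(uni, list(x = comp, y = comp, z = comp),
    list(vesicle_edge("x", "y", lab), vesicle_edge("y", "z", lab)))
  r <- check_same_label_same_target(net_bad)
  expect_false(r$ok)
  expect_match(r$violations, "different nodes")
  net_distinct <- transport_network(uni, list(x = comp, y = comp, z = comp),
    list(vesicle_edge("x", "y", c(1L, 0L)), vesicle_edge("y", "z", c(0L, 1L))))
  expect_true(check_same_label_same_target(net_distinct)$ok)
})

test_that("steady-state cycle witnesses satisfy their invariants", {
  net <- two_node_shuttle()
  ss <- steady_state_cycles(net)
  expect_true(ss$ok)
  expect_length(ss$witnesses, 2L)
  for (w in ss$witnesses) {
    expect_equal(w$nodes[1], net$edge_src[w$edge])
    expect_equal(w$nodes[2], net$edge_tgt[w$edge])
    expect_true(length(w$nodes) >= 2 && length(w$nodes) <= length(net$node_ids))
    # molecule present on every node and every edge of the cycle
    for (nd in w$nodes) expect_equal(unname(net$node_comp[nd, w$molecule]), 1L)
    for (e in w$edges) expect_equal(net$edge_comp[e, w$molecule], 1L)
    # consecutive hops (and the closing hop) use matching edges
    hops <- c(w$nodes, w$nodes[1])
    for (i in seq_along(w$edges)) {
      expect_equal(net$edge_src[w$edges[i]], hops[i])
      expect_equal(net$edge_tgt[w$edges[i]], hops[i + 1])
    }
  }
  expect_false(steady_state_cycles(one_way_net())$ok)
})

test_that("cycle and SCC formulations of steady state agree", {
  # exhaustive over 2-node networks at M = 2
  count <- 0L
  for (tp in topologies_with_edges(2)) {
    slots <- list()
    for (u in 1:2) for (v in 1:2)
      if (u != v && tp$mult[u, v] > 0)
        for (s in seq_len(tp$mult[u, v]))
          slots[[length(slots) + 1L]] <- c(u, v)
    labelings <- expand.grid(rep(list(1:3), length(slots)))
    for (xc in 0:15) {
      comps <- list(n1 = c(bitwAnd(xc, 1L) > 0, bitwAnd(xc, 2L) > 0) * 1L,
                    n2 = c(bitwAnd(xc, 4L) > 0, bitwAnd(xc, 8L) > 0) * 1L)
      for (r in seq_len(nrow(labelings))) {
        edges <- list(); bad <- FALSE
        for (si in seq_along(slots)) {
          comp <- c(bitwAnd(labelings[r, si], 1L) > 0,
                    bitwAnd(labelings[r, si], 2L) > 0) * 1L
          src <- comps[[slots[[si]][1]]]
          if (any(comp > src)) { bad <- TRUE; break }
          edges[[si]] <- vesicle_edge(paste0("n", slots[[si]][1]),
                                      paste0("n", slots[[si]][2]), comp)
        }
        if (bad) next
        net <- tryCatch(transport_network(u2, comps, edges),
                        error = function(e) NULL)
        if (is.null(net)) next
        count <- count + 1L
        expect_equal(steady_state_cycles(net)$ok, steady_state_scc(net))
      }
    }
  }
  expect_gt(count, 100L)
  # randomized over 3-node networks
  for (seed in 1:150) {
    net <- random_network(3, 2, seed)
    expect_equal(steady_state_cycles(net)$ok, steady_state_scc(net))
  }
})

test_that("assign_fluxes conserves every molecule at every node", {
  for (seed in 1:80) {
    net <- random_network(3, 2, seed + 500)
    if (!steady_state_cycles(net)$ok) next
    flux <- assign_fluxes(net)
    expect_true(all((flux > 0) == (net$edge_comp == 1L)))
    for (m in seq_len(net$universe$M)) for (id in net$node_ids) {
      inflow <- sum(flux[net$edge_tgt == id, m])
      outflow <- sum(flux[net$edge_src == id, m])
      expect_lt(abs(inflow - outflow), 1e-9)
    }
  }
  expect_error(assign_fluxes(one_way_net()), "steady state")
})

test_that("validate_instance combines structural and semantic checks", {
  inst <- build_fixture("row2_two_compartment")
  val <- validate_instance(inst)
  expect_true(val$pass)
  # all-pass implies strong connectivity and underlying connectivity >= 2
  expect_true(is_strongly_connected(inst$network))
  expect_gte(edge_connectivity(underlying_multigraph(inst$network)), 2)
  # mutate an edge composition outside its source: structural failure
  bad <- inst
  missing <- which(bad$network$node_comp[bad$network$edge_src[1], ] == 0L)
  expect_gt(length(missing), 0L)
  bad$network$edge_comp[1, missing[1]] <- 1L
  vb <- validate_instance(bad)
  expect_false(vb$structural_ok)
  expect_true(is.na(vb$c1_steady_state))
  # any unregulated (none/none) instance with >= 1 edge fails C1-C3
  for (tp in topologies_with_edges(2, strong = TRUE)) {
    v <- solve_fixed(tp$mult, regime_row(6), 4)
    expect_equal(v$status, "UNSAT")
  }
})
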