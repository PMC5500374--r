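# Shared builders for tests: small hand-made networks, random
# labeled networks (type-invariant: edge labels are subsets of their
# sources), and a brute-force CNF satisfiability checker.

u2 <- molecule_universe(2)
u4 <- molecule_universe(4)
u6 <- molecule_universe(6)

# two compartments exchanging molecule 1 in both directions
two_node_shuttle <- function(M = 2) {
  uni <- molecule_universe(M)
  comp <- c(1L, rep(0L, M - 1L))
  transport_network(uni,
    list(x = comp, y = comp),
    list(vesicle_edge("x", "y", comp), vesicle_edge("y", "x", comp)))
}

# x -> y carrying molecule 1, nothing returning
one_way_net <- function(M = 2) {
  uni <- molecule_universe(M)
  comp <- c(1L, rep(0L, M - 1L))
  transport_network(uni, list(x = comp, y = comp),
                    list(vesicle_edge("x", "y", comp)))
}

# random structurally-valid network on a random topology
random_network <- function(n, M, seed) {
  set.seed(seed)
  uni <- molecule_universe(M)
  ids <- paste0("n", seq_len(n))
  comps <- setNames(lapply(seq_len(n), function(i)
    sample(0:1, M, replace = TRUE)), ids)
  edges <- list()
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u == v) next
    for (s in seq_len(sample(0:2, 1))) {
      src <- comps[[ids[u]]]
      if (!sum(src)) next
      comp <- integer(M)
      present <- which(src == 1L)
      take <- present[sample(c(TRUE, FALSE), length(present), replace = TRUE)]
      if (!length(take)) take <- present[sample.int(length(present), 1L)]
      comp[take] <- 1L
      edges[[length(edges) + 1L]] <- vesicle_edge(ids[u], ids[v], comp)
    }
  }
  # drop duplicate parallel labels to respect the type invariant
  keep <- rep(TRUE, length(edges))
  seen <- character()
  for (i in seq_along(edges)) {
    key <- paste(edges[[i]]$source, edges[[i]]$target,
                 paste(edges[[i]]$composition, collapse = ""))
    if (key %in% seen) keep[i] <- FALSE else seen <- c(seen, key)
  }
  transport_network(uni, comps, edges[keep])
}

# brute-force CNF satisfiability over <= 20 variables
brute_sat <- function(nvars, clauses) {
  for (mask in 0:(2^nvars - 1)) {
    assign <- as.logical(bitwAnd(mask, 2^(0:(nvars - 1))))
    ok <- all(vapply(clauses, function(cl)
      any((cl > 0 & assign[abs(cl)]) | (cl < 0 & !assign[abs(cl)])), TRUE))
    if (ok) return(TRUE)
  }
  FALSE
}

# all multiplicity-capped topologies on n nodes with >= 1 edge
topologies_with_edges <- function(n, strong = FALSE) {
  b <- search_bounds(n, 2, strongly_connected_only = strong)
  Filter(function(tp) sum(tp$mult) > 0, enumerate_topologies(b))
}

solve_fixed <- function(topology, regime, M, seed = 0) {
  enc <- encode_feasibility(search_bounds(nrow(topology), M), regime,
                            fixed_topology = topology)
  solve_cnf(enc$cnf, seed = seed)
}
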