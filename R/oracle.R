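# Brute-force exhaustive feasibility oracle for tiny topologies:
# independent ground truth for the SAT encoding.

#' Brute-force feasibility decision
#'
#' Decides exhaustively whether a fixed directed-multigraph topology
#' admits any valid steady-state labeling under the regime: iterates
#' all node compositions (canonical under permutations of molecule
#' types within the Q block and within the R block — the model is
#' equivariant under such relabelings), all pairing matrices, and all
#' edge labelings consistent with the structural rules, deciding
#' regulation-function existence exactly per composition class
#' (functional consistency makes activity a per-(side, composition)
#' choice). Completely independent of the CNF encoding.
#'
#' @param topology n x n multiplicity matrix, n <= 3.
#' @param regime a [regulation_regime()].
#' @param M even molecule count <= 4.
#' @param budget work budget (search-tree nodes); the oracle refuses
#'   (with an error) when exceeded.
#' @return `vt_feasibility`: list(feasible, explored, witness) where
#'   witness is a validated [network_instance()] when feasible.
#' @export
brute_force_feasible <- function(topology, regime, M, budget = 5e8) {
  topology <- as.matrix(topology)
  comp_rule <- match(regime$compartment_rule, c("none", "boolean")) - 1L
  ves_rule <- match(regime$vesicle_rule,
                    c("none", "boolean", "snare_inhibition")) - 1L
  res <- .oracle_cpp(topology, as.integer(M), comp_rule, ves_rule,
                     as.numeric(budget))
  if (identical(res$status, "budget"))
    stop(sprintf(
      "oracle work budget exceeded (%.0f nodes explored); the %d-node, M=%d search space is too large",
      res$explored, nrow(topology), M))
  witness <- NULL
  if (identical(res$status, "feasible"))
    witness <- oracle_witness_to_instance(res$witness, regime, M)
  structure(list(feasible = identical(res$status, "feasible"),
                 explored = res$explored, witness = witness),
            class = "vt_feasibility")
}

# convert the C++ witness (bitmask compositions) into a full instance
oracle_witness_to_instance <- function(w, regime, M) {
  uni <- molecule_universe(M)
  bits <- function(mask) as.integer(bitwAnd(mask, 2^(seq_len(M) - 1L)) > 0)
  n <- length(w$node_comp)
  ids <- paste0("n", seq_len(n))
  comps <- setNames(lapply(w$node_comp, bits), ids)
  E <- length(w$edge_comp)
  edges <- lapply(seq_len(E), function(i)
    vesicle_edge(ids[w$edges[i, 1]], ids[w$edges[i, 2]], bits(w$edge_comp[i])))
  net <- transport_network(uni, comps, edges, check = FALSE)
  pairing <- pairing_matrix(w$pairing, uni)
  reg <- NULL
  if (regime$compartment_rule == "boolean" || regime$vesicle_rule == "boolean") {
    cmap <- NULL; vmap <- NULL
    if (regime$compartment_rule == "boolean") {
      cmap <- character()
      for (v in seq_len(n))
        cmap[comp_to_string(bits(w$node_comp[v]), space = FALSE)] <-
          comp_to_string(bits(w$node_act[v]), space = FALSE)
    }
    if (regime$vesicle_rule == "boolean") {
      vmap <- character()
      for (i in seq_len(E))
        vmap[comp_to_string(bits(w$edge_comp[i]), space = FALSE)] <-
          comp_to_string(bits(w$edge_act[i]), space = FALSE)
    }
    reg <- regulation_function(compartment = cmap, vesicle = vmap)
  }
  network_instance(net, pairing, regime, reg)
}
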