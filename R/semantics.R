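# Executable semantics of the RSS model: SNARE activity under the
# regulation regimes, fusion competence, the fusion-rule checks (C2,
# C3), the steady-state condition (C1) with explicit cycle witnesses,
# and constructive flux assignment.

#' Active molecules on a membrane
#'
#' Applies the side's regulation rule to a composition and returns the
#' active subset. Under `"none"` every present molecule is active.
#' Under `"boolean"` the explicit regulation map is consulted (missing
#' compositions default to all-inactive) and clipped to presence.
#' Under `"snare_inhibition"` (vesicle side only) molecule i is
#' inactive iff some j present on the same membrane has a pairing entry
#' with i in either orientation.
#'
#' @param comp composition vector.
#' @param side `"compartment"` or `"vesicle"`.
#' @param regime a [regulation_regime()].
#' @param pairing a [pairing_matrix()].
#' @param reg a [regulation_function()]; required iff the side's rule is
#'   `"boolean"`.
#' @return integer 0/1 activity vector (a subset of `comp`).
#' @export
active_molecules <- function(comp, side, regime, pairing, reg = NULL) {
  side <- match.arg(side, c("compartment", "vesicle"))
  rule <- if (side == "compartment") regime$compartment_rule else regime$vesicle_rule
  if (rule == "snare_inhibition" && side == "compartment")
    stop("SNARE-SNARE inhibition is not defined on the compartment side")
  comp <- as.integer(comp)
  switch(rule,
    none = comp,
    snare_inhibition = {
      present <- which(comp == 1L)
      act <- integer(length(comp))
      for (i in present) {
        partners <- pairing[i, ] | pairing[, i]
        if (!any(partners & comp == 1L)) act[i] <- 1L
      }
      act
    },
    boolean = {
      if (is.null(reg)) stop("boolean regulation requires a regulation function")
      map <- if (side == "compartment") reg$compartment else reg$vesicle
      key <- comp_to_string(comp, space = FALSE)
      a <- if (!is.null(map) && key %in% names(map))
        comp_from_string(map[[key]], length(comp)) else integer(length(comp))
      as.integer(a & comp)   # active implies present
    })
}

#' Fusion competence
#'
#' TRUE iff some active molecule on the vesicle membrane pairs (in the
#' vesicle -> compartment orientation of the pairing matrix) with some
#' active molecule on the compartment membrane. A single active SNARE
#' pair is necessary and sufficient for fusion.
#'
#' @param vesicle_active,compartment_active 0/1 activity vectors.
#' @param pairing a [pairing_matrix()].
#' @return logical.
#' @export
fusion_competent <- function(vesicle_active, compartment_active, pairing) {
  vi <- which(vesicle_active == 1L)
  ci <- which(compartment_active == 1L)
  if (!length(vi) || !length(ci)) return(FALSE)
  any(pairing[vi, ci, drop = FALSE] == 1L)
}

# per-instance activity helpers ------------------------------------------

instance_edge_active <- function(instance, i) {
  active_molecules(instance$network$edge_comp[i, ], "vesicle",
                   instance$regime, instance$pairing, instance$regulation)
}

instance_node_active <- function(instance, id) {
  active_molecules(instance$network$node_comp[id, ], "compartment",
                   instance$regime, instance$pairing, instance$regulation)
}

#' Fusion-rule checks
#'
#' `check_edges_valid()`: every edge must be fusion-competent with its
#' own target (C2, first half). `check_same_label_same_target()`: two
#' edges of identical composition must share a target — identical
#' vesicles have identical destinations (C2, second half).
#' `check_topology_respect()`: no edge may be fusion-competent with any
#' node other than its target, including its own source (C3).
#'
#' @param instance a [network_instance()].
#' @return list with `ok` (logical) and `violations` (character).
#' @export
check_edges_valid <- function(instance) {
  net <- instance$network
  viol <- character()
  for (i in seq_along(net$edge_src)) {
    va <- instance_edge_active(instance, i)
    ta <- instance_node_active(instance, net$edge_tgt[i])
    if (!fusion_competent(va, ta, instance$pairing))
      viol <- c(viol, sprintf(
        "edge %d (%s->%s [%s]) is not fusion-competent with its target",
        i, net$edge_src[i], net$edge_tgt[i], comp_to_string(net$edge_comp[i, ])))
  }
  list(ok = length(viol) == 0, violations = viol)
}

#' @rdname check_edges_valid
#' @param network a [transport_network()].
#' @export
check_same_label_same_target <- function(network) {
  viol <- character()
  E <- length(network$edge_src)
  if (E >= 2) {
    labs <- apply(network$edge_comp, 1, paste, collapse = "")
    for (l in unique(labs)) {
      idx <- which(labs == l)
      tg <- unique(network$edge_tgt[idx])
      if (length(tg) > 1)
        viol <- c(viol, sprintf(
          "edges with identical composition [%s] target different nodes: %s",
          comp_to_string(network$edge_comp[idx[1], ]), paste(tg, collapse = ", ")))
    }
  }
  list(ok = length(viol) == 0, violations = viol)
}

#' @rdname check_edges_valid
#' @export
check_topology_respect <- function(instance) {
  net <- instance$network
  viol <- character()
  for (i in seq_along(net$edge_src)) {
    va <- instance_edge_active(instance, i)
    for (z in net$node_ids) {
      if (z == net$edge_tgt[i]) next
      za <- instance_node_active(instance, z)
      if (fusion_competent(va, za, instance$pairing))
        viol <- c(viol, sprintf(
          "edge %d (%s->%s [%s]) is fusion-competent with non-target node %s",
          i, net$edge_src[i], net$edge_tgt[i],
          comp_to_string(net$edge_comp[i, ]), z))
    }
  }
  list(ok = length(viol) == 0, violations = viol)
}

#' Steady-state condition with cycle witnesses
#'
#' The homeostasis requirement: every molecule leaving a compartment on
#' a vesicle must return to it in a cycle, the molecule being present
#' on every edge and every node of the path taken. For each (edge,
#' molecule) pair a witness node sequence `a1..an` (`2 <= n <= N`) is
#' produced with `a1` the edge's source, `a2` its target, consecutive
#' nodes (and `an -> a1`) joined by molecule-carrying edges.
#'
#' @param network a [transport_network()].
#' @return list with `ok`, `witnesses` (list of
#'   `list(edge, molecule, nodes, edges)`; complete when `ok`) and
#'   `violations`.
#' @export
steady_state_cycles <- function(network) {
  M <- network$universe$M
  ids <- network$node_ids
  E <- length(network$edge_src)
  witnesses <- list()
  viol <- character()
  for (m in seq_len(M)) {
    carrying <- which(network$edge_comp[, m] == 1L)
    if (!length(carrying)) next
    has_m <- ids[network$node_comp[, m] == 1L]
    # adjacency within the m-subgraph (nodes and edges carrying m)
    sub_e <- carrying[network$edge_src[carrying] %in% has_m &
                      network$edge_tgt[carrying] %in% has_m]
    adj <- lapply(setNames(vector("list", length(has_m)), has_m),
                  function(x) integer(0))
    for (e in sub_e) adj[[network$edge_src[e]]] <-
        c(adj[[network$edge_src[e]]], e)
    for (e in carrying) {
      src <- network$edge_src[e]; tgt <- network$edge_tgt[e]
      w <- NULL
      if (src %in% has_m && tgt %in% has_m && e %in% sub_e) {
        path <- bfs_path(adj, network, tgt, src)
        if (!is.null(path)) {
          # nodes: src, tgt, intermediate nodes of the return path
          nodes <- c(src, path$nodes[-length(path$nodes)])
          w <- list(edge = e, molecule = m, nodes = nodes,
                    edges = c(e, path$edges))
        }
      }
      if (is.null(w)) {
        viol <- c(viol, sprintf(
          "molecule %d on edge %d (%s->%s) completes no cycle", m, e, src, tgt))
      } else witnesses[[length(witnesses) + 1L]] <- w
    }
  }
  list(ok = length(viol) == 0, witnesses = witnesses, violations = viol)
}

# BFS from `from` to `to` (distinct nodes) within an adjacency list of
# edge indices; returns list(nodes, edges) for the shortest path
# from -> ... -> to, or NULL when unreachable
bfs_path <- function(adj, network, from, to) {
  prev_edge <- setNames(rep(NA_integer_, length(adj)), names(adj))
  seen <- setNames(logical(length(adj)), names(adj))
  queue <- from; seen[from] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur == to) {
      nodes <- character(); edges <- integer()
      at <- to
      while (at != from) {
        e <- prev_edge[[at]]
        nodes <- c(at, nodes); edges <- c(e, edges)
        at <- network$edge_src[e]
      }
      return(list(nodes = c(from, nodes), edges = edges))
    }
    for (e in adj[[cur]]) {
      nxt <- network$edge_tgt[e]
      if (!seen[[nxt]]) {
        seen[[nxt]] <- TRUE
        prev_edge[[nxt]] <- e
        queue <- c(queue, nxt)
      }
    }
  }
  NULL
}

#' Steady state via strongly connected components
#'
#' Equivalent formulation used as an independent oracle for
#' [steady_state_cycles()]: for every molecule m, every edge carrying m
#' must have both endpoints carrying m and lying in the same strongly
#' connected component of the m-subgraph (edges carrying m restricted
#' to nodes carrying m).
#'
#' @param network a [transport_network()].
#' @return logical.
#' @export
steady_state_scc <- function(network) {
  M <- network$universe$M
  ids <- network$node_ids
  for (m in seq_len(M)) {
    carrying <- which(network$edge_comp[, m] == 1L)
    if (!length(carrying)) next
    has_m <- ids[network$node_comp[, m] == 1L]
    if (!all(network$edge_src[carrying] %in% has_m) ||
        !all(network$edge_tgt[carrying] %in% has_m)) return(FALSE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = network$edge_src[carrying],
                 to = network$edge_tgt[carrying]),
      directed = TRUE, vertices = data.frame(name = has_m))
    comp <- igraph::components(g, mode = "strong")$membership
    if (any(comp[network$edge_src[carrying]] !=
            comp[network$edge_tgt[carrying]])) return(FALSE)
  }
  TRUE
}

#' Constructive flux assignment
#'
#' Builds positive real fluxes realizing the steady state: one unit of
#' flux is routed around the witness cycle of every (edge, molecule)
#' pair and contributions are summed per edge. The result satisfies
#' exact per-molecule conservation at every node and is positive
#' exactly where the molecule is carried.
#'
#' @param network a [transport_network()] passing [steady_state_cycles()].
#' @return E x M numeric flux matrix.
#' @export
assign_fluxes <- function(network) {
  ss <- steady_state_cycles(network)
  if (!ss$ok)
    stop("network is not in steady state: ", ss$violations[1])
  E <- length(network$edge_src); M <- network$universe$M
  flux <- matrix(0, E, M)
  for (w in ss$witnesses)
    for (e in w$edges) flux[e, w$molecule] <- flux[e, w$molecule] + 1.0
  flux
}

#' Validate a network instance
#'
#' Structural invariants plus the three semantic conditions: C1 the
#' steady-state (cycle) condition, C2 the fusion rules (every edge
#' competent with its target, identical labels share a target), C3
#' topology respect (no competence with non-targets). Semantic flags
#' are NA when the instance is structurally malformed.
#'
#' @param instance a [network_instance()].
#' @return `vt_validation`: flags `structural_ok`, `c1_steady_state`,
#'   `c2_fusion_valid`, `c3_topology_respected`, overall `pass`, and
#'   `violations`.
#' @export
validate_instance <- function(instance) {
  viol <- network_structural_violations(instance$network)
  needs_reg <- instance$regime$compartment_rule == "boolean" ||
    instance$regime$vesicle_rule == "boolean"
  if (needs_reg && is.null(instance$regulation))
    viol <- c(viol, "boolean regulation requested but no regulation function given")
  if (!needs_reg && !is.null(instance$regulation))
    viol <- c(viol, "regulation function given but no side has a boolean rule")
  structural_ok <- length(viol) == 0
  if (!structural_ok) {
    return(structure(list(structural_ok = FALSE, c1_steady_state = NA,
                          c2_fusion_valid = NA, c3_topology_respected = NA,
                          pass = FALSE, violations = viol),
                     class = "vt_validation"))
  }
  ss <- steady_state_cycles(instance$network)
  ev <- check_edges_valid(instance)
  sl <- check_same_label_same_target(instance$network)
  tr <- check_topology_respect(instance)
  viol <- c(ss$violations, ev$violations, sl$violations, tr$violations)
  structure(list(structural_ok = TRUE,
                 c1_steady_state = ss$ok,
                 c2_fusion_valid = ev$ok && sl$ok,
                 c3_topology_respected = tr$ok,
                 pass = ss$ok && ev$ok && sl$ok && tr$ok,
                 violations = viol),
            class = "vt_validation")
}

#' @export
print.vt_validation <- function(x, ...) {
  flag <- function(v) if (isTRUE(v)) "PASS" else if (isFALSE(v)) "FAIL" else "--"
  cat("Instance validation:", if (x$pass) "PASS" else "FAIL", "\n")
  cat("  structural:       ", flag(x$structural_ok), "\n")
  cat("  C1 steady state:  ", flag(x$c1_steady_state), "\n")
  cat("  C2 fusion rules:  ", flag(x$c2_fusion_valid), "\n")
  cat("  C3 topology:      ", flag(x$c3_topology_respected), "\n")
  for (v in x$violations) cat("  -", v, "\n")
  invisible(x)
}
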