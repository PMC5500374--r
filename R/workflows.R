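# Necessity / sufficiency workflows: which degree of underlying
# k-edge-connectivity a regulation regime requires, and whether every
# sufficiently connected topology is feasible.

regime_label <- function(regime)
  paste0(regime$compartment_rule, "/", regime$vesicle_rule)

# feasibility query with free structure on exactly `n` nodes under the
# given connectivity option; returns the solve verdict plus encoding
free_structure_query <- function(bounds, regime, n, connectivity, seed,
                                 max_conflicts = -1) {
  b <- bounds
  b$connectivity <- connectivity
  b$strongly_connected_only <- TRUE
  enc <- encode_feasibility(b, regime, nodes = n)
  v <- solve_cnf(enc$cnf, seed = seed, max_conflicts = max_conflicts)
  list(verdict = v, encoding = enc)
}

# unit-clause assumptions pinning the structure variables of a
# free-structure encoding to a concrete topology
topology_assumptions <- function(vm, mult) {
  n <- nrow(mult)
  assume <- integer(0)
  for (u in seq_len(n)) for (v in seq_len(n)) if (u != v) {
    p <- vm$pidx[u, v]
    assume <- c(assume,
                if (mult[u, v] >= 1L) vm$ev(p, 1L) else -vm$ev(p, 1L),
                if (mult[u, v] >= 2L) vm$ev(p, 2L) else -vm$ev(p, 2L))
  }
  assume
}

# decide whether any feasible instance exists on exactly n nodes whose
# underlying connectivity matches `connectivity` (NULL = any strongly
# connected). The free-structure query is tried first under a conflict
# budget; if the solver cannot settle it (symmetric UNSAT proofs can
# be deep), the question is decomposed exactly over enumerated
# topology classes with structure pinned per class.
feasible_on_level <- function(regime, bounds, n, connectivity, seed,
                              budget = 30000) {
  if (n > 4) budget <- -1   # no exhaustive enumeration beyond 4 nodes:
                            # run the free query to completion
  q <- free_structure_query(bounds, regime, n, connectivity, seed,
                            max_conflicts = budget)
  if (q$verdict$status == "SAT")
    return(list(feasible = TRUE, verdict = q$verdict, encoding = q$encoding))
  if (q$verdict$status == "UNSAT")
    return(list(feasible = FALSE))
  # UNKNOWN: per-topology decomposition (node symmetry eliminated)
  b <- bounds
  b$strongly_connected_only <- TRUE
  b$connectivity <- connectivity
  topos <- enumerate_topologies(b, nodes = n)
  base <- encode_feasibility(bounds, regime, nodes = n)
  for (tp in topos) {
    v <- solve_cnf(base$cnf, seed = seed,
                   assumptions = topology_assumptions(base$varmap, tp$mult))
    if (v$status == "SAT")
      return(list(feasible = TRUE, verdict = v, encoding = base))
  }
  list(feasible = FALSE)
}

#' Necessity of k-edge-connectivity
#'
#' Checks the two halves of the necessity argument for a regime within
#' bounds: a SAT query for the existence of a feasible network whose
#' underlying multigraph is at least k-connected, and a SAT query for a
#' feasible network that is connected but below k (the generalized
#' "k-1-connected but not k" pattern). Necessity of k is confirmed
#' when the first succeeds and the second is unsatisfiable. Node
#' counts 2..`bounds$max_nodes` are swept.
#'
#' @param regime a [regulation_regime()].
#' @param k integer >= 2.
#' @param bounds a [search_bounds()].
#' @param seed solver seed.
#' @return `vt_necessity`: list(exists_at_k, exists_below_k, witness,
#'   necessary).
#' @export
check_necessary <- function(regime, k, bounds, seed = 0) {
  if (k < 2) stop("k must be >= 2")
  witness <- NULL
  exists_at_k <- FALSE
  for (n in 2:bounds$max_nodes) {
    r <- feasible_on_level(regime, bounds, n,
                           list(type = "geq", k = as.integer(k)), seed)
    if (r$feasible) {
      exists_at_k <- TRUE
      witness <- decode_instance(r$verdict, r$encoding)
      break
    }
  }
  exists_below_k <- FALSE
  for (n in 2:bounds$max_nodes) {
    r <- feasible_on_level(regime, bounds, n,
                           list(type = "below", k = as.integer(k)), seed)
    if (r$feasible) { exists_below_k <- TRUE; break }
  }
  structure(list(regime = regime, k = k, exists_at_k = exists_at_k,
                 exists_below_k = exists_below_k, witness = witness,
                 necessary = exists_at_k && !exists_below_k),
            class = "vt_necessity")
}

#' @export
print.vt_necessity <- function(x, ...) {
  cat(sprintf("Necessity of %d-connectedness under %s: %s\n", x$k,
              regime_label(x$regime),
              if (x$necessary) "CONFIRMED" else "NOT confirmed"))
  cat(sprintf("  feasible at >= %d-connected: %s\n", x$k, x$exists_at_k))
  cat(sprintf("  feasible below %d-connected: %s\n", x$k, x$exists_below_k))
  invisible(x)
}

#' Sufficiency of k-edge-connectivity
#'
#' Enumerates (up to isomorphism) every strongly connected directed
#' multigraph topology within bounds whose underlying multigraph is at
#' least k-edge-connected, and runs the existential SAT feasibility
#' check on each with structure pinned to the topology. Sufficiency
#' holds when every such topology is feasible. A non-strongly-connected
#' digraph can never reach steady state, so the universal claim is
#' quantified over strongly connected topologies (an
#' `undirected_mode` also accepts a topology class if ANY orientation
#' sharing its underlying multigraph is feasible).
#'
#' @inheritParams check_necessary
#' @param stop_at_first stop at the first infeasible topology.
#' @param undirected_mode quantify over underlying undirected classes
#'   (weaker reading; default FALSE).
#' @return `vt_sufficiency`: list(all_feasible, checked_count,
#'   counterexamples).
#' @export
check_sufficient <- function(regime, k, bounds, seed = 0,
                             stop_at_first = FALSE, undirected_mode = FALSE) {
  if (k < 2) stop("k must be >= 2")
  checked <- 0L
  counterexamples <- list()
  for (n in 2:bounds$max_nodes) {
    b <- bounds
    b$strongly_connected_only <- TRUE
    b$connectivity <- list(type = "geq", k = as.integer(k))
    topos <- enumerate_topologies(b, nodes = n)
    if (!length(topos)) next
    base <- encode_feasibility(bounds, regime, nodes = n,
                               fixed_topology = NULL)
    vm <- base$varmap
    if (undirected_mode) {
      und_key <- vapply(topos, function(tp)
        .topo_canon_cpp(tp$mult + t(tp$mult)), "")
      groups <- split(seq_along(topos), und_key)
    } else {
      groups <- as.list(seq_along(topos))
    }
    for (grp in groups) {
      any_feasible <- FALSE
      for (ti in grp) {
        tp <- topos[[ti]]
        assume <- integer(0)
        for (u in seq_len(n)) for (v in seq_len(n)) if (u != v) {
          p <- vm$pidx[u, v]
          assume <- c(assume,
                      if (tp$mult[u, v] >= 1L) vm$ev(p, 1L) else -vm$ev(p, 1L),
                      if (tp$mult[u, v] >= 2L) vm$ev(p, 2L) else -vm$ev(p, 2L))
        }
        v <- solve_cnf(base$cnf, seed = seed, assumptions = assume)
        checked <- checked + 1L
        if (v$status == "SAT") { any_feasible <- TRUE; break }
      }
      if (!any_feasible) {
        counterexamples[[length(counterexamples) + 1L]] <- topos[[grp[1]]]
        if (stop_at_first)
          return(structure(list(regime = regime, k = k, all_feasible = FALSE,
                                checked_count = checked,
                                counterexamples = counterexamples),
                           class = "vt_sufficiency"))
      }
    }
  }
  structure(list(regime = regime, k = k,
                 all_feasible = length(counterexamples) == 0,
                 checked_count = checked,
                 counterexamples = counterexamples),
            class = "vt_sufficiency")
}

#' @export
print.vt_sufficiency <- function(x, ...) {
  cat(sprintf("Sufficiency of %d-connectedness under %s: %s\n", x$k,
              regime_label(x$regime),
              if (x$all_feasible) "CONFIRMED" else "REFUTED"))
  cat(sprintf("  topologies checked: %d, counterexamples: %d\n",
              x$checked_count, length(x$counterexamples)))
  invisible(x)
}

#' Minimum feasible connectivity
#'
#' The least underlying edge connectivity over all feasible
#' steady-state instances within bounds, or NULL when no instance is
#' feasible. With the SAT engine, feasibility at each exact
#' connectivity level c = 2, 3, ... is decided by free-structure
#' queries over node counts 2..max_nodes; with the oracle engine,
#' strongly connected topologies are enumerated and decided
#' exhaustively (tiny bounds only).
#'
#' @inheritParams check_necessary
#' @param engine `"sat"` or `"oracle"`.
#' @param molecule_sweep optional increasing even molecule counts to
#'   try at each level (defaults to `bounds$molecules` only).
#' @return integer minimum connectivity, or NULL.
#' @export
min_feasible_connectivity <- function(regime, bounds,
                                      engine = c("sat", "oracle"),
                                      seed = 0, molecule_sweep = NULL) {
  engine <- match.arg(engine)
  if (is.null(molecule_sweep)) molecule_sweep <- bounds$molecules
  if (engine == "oracle") {
    best <- Inf
    for (n in 2:bounds$max_nodes) {
      b <- bounds; b$strongly_connected_only <- TRUE
      for (tp in enumerate_topologies(b, nodes = n)) {
        if (tp$connectivity >= best) next
        for (M in molecule_sweep) {
          r <- brute_force_feasible(tp$mult, regime, M)
          if (r$feasible) { best <- min(best, tp$connectivity); break }
        }
      }
    }
    return(if (is.finite(best)) as.integer(best) else NULL)
  }
  cmax <- 2L * bounds$max_multiplicity * (bounds$max_nodes - 1L)
  for (cc in 2:cmax) {
    for (n in 2:bounds$max_nodes) {
      if (cc > 2L * bounds$max_multiplicity * (n - 1L)) next
      for (M in molecule_sweep) {
        b <- bounds; b$molecules <- as.integer(M)
        r <- feasible_on_level(regime, b, n,
                               list(type = "exact", k = as.integer(cc)), seed)
        if (r$feasible) return(as.integer(cc))
      }
    }
  }
  NULL
}
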