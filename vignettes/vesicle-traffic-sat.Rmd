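---
title: "Methods: SNARE-regulated vesicle traffic networks as a SAT problem"
author: "snaresat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNARE-regulated vesicle traffic networks as a SAT problem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snaresat)
```

## The model

A eukaryotic cell maintains membrane-bound compartments that exchange
material through vesicles. `snaresat` works with the standard abstract
description of this system (the Rothman-Schekman-Sudhof picture):

* Compartments are nodes of a directed multigraph; vesicle routes are
  directed edges. Self edges are not permitted, and at most two
  parallel edges may join an ordered node pair.
* There are `M` molecular types, the first half Q-SNAREs, the second
  half R-SNAREs (`M` is even). Every membrane — compartment or vesicle
  — is labeled by the subset of types it carries. An edge may carry
  only molecules present on its source compartment, and must carry at
  least one molecule.
* Fusion is driven by SNARE pairing: an `M x M` binary pairing matrix
  marks fusion-competent (vesicle molecule, compartment molecule)
  combinations; entries exist only for Q-R and R-Q combinations and
  the matrix need not be symmetric, because the vesicle and
  compartment surfaces are physically different environments. A single
  active pair is necessary and sufficient for fusion.
* Regulation: a molecule's activity on a membrane may depend on the
  other molecules on the same membrane. The package implements the
  three rules — `none` (every present molecule is active), `boolean`
  (activity is an arbitrary Boolean function of the membrane
  composition, one function per molecule per side, identical across
  the cell), and `snare_inhibition` (vesicle side only: a molecule is
  inactivated by a co-present pairing partner in either orientation of
  the matrix, because the disassembly machinery that unzips SNARE
  bundles is absent from vesicles). Six compartment/vesicle rule
  combinations arise; `regime_row(1)` through `regime_row(6)` follow
  the conventional table order.
* Steady state: every molecule leaving a compartment must return to
  it, i.e. for each (edge, molecule) pair there is a cycle whose edges
  and nodes all carry the molecule. Positive fluxes realizing the
  steady state then always exist (`assign_fluxes()` constructs them).

A `NetworkInstance` bundles a labeled graph, a pairing matrix, a
regime, and (for Boolean rules) explicit regulation maps.
`validate_instance()` checks the three semantic conditions that the
feasibility machinery also enforces: C1, steady-state cycles; C2,
every edge fuses with its own target and identical vesicle labels
share a target (identical vesicles are physically indistinguishable,
so they must have one destination); C3, no edge is fusion-competent
with any compartment other than its target, including its own source.

## Why connectivity

For a network in steady state every carried molecule moves in closed
cycles, so the transport graph must be strongly connected, and its
underlying undirected multigraph must be at least 2-edge-connected
(every set of compartments with an incoming route needs an outgoing
one). The interesting question is the converse: which degree of
k-edge-connectivity is *necessary* (no feasible network below it) and
*sufficient* (every graph at that level supports some labeling) under
each regulation regime. `check_necessary()`, `check_sufficient()` and
`min_feasible_connectivity()` decide these questions exhaustively
within finite bounds.

## The feasibility engine

`encode_feasibility()` translates bounded feasibility into CNF whose
models are exactly the valid instances; a bundled CDCL SAT solver
(watched literals, first-UIP clause learning, VSIDS, Luby restarts)
decides it. Design choices that matter:

* **Boolean regulation without truth tables.** A Boolean function over
  `M` inputs has `2^(2^M)` possibilities; enumerating them is
  hopeless. Instead, activity bits are free variables constrained by
  *functional consistency*: two membranes of the same side with equal
  compositions must have equal activity. This represents exactly the
  extensional content of "activity is a function of composition" over
  the membranes that actually occur.
* **Steady state by step-indexed reachability.** `reach_t(m, a, b)`
  ("b reachable from a within t hops of the m-subgraph") is defined
  with biconditional clauses and unrolled to `N-1` steps, so the
  solver cannot over-approximate reachability; simple paths never need
  more hops. The cycle-witness formulation lives independently in
  `steady_state_cycles()` and the equivalence of the two is a tested
  property, not an assumption.
* **Connectivity as subset cuts.** For `N <= 8` nodes, the
  `2^(N-1)-1` node bipartitions are enumerated and each crossing edge
  count constrained with sequential-counter cardinality encodings;
  "connectivity exactly c" adds selector-guarded "some cut `<= c`"
  constraints. Exact, no approximation.
* **Symmetry breaking.** The model is equivariant under relabeling
  molecule types within the Q block, within the R block, and (for
  free-structure queries) under node relabeling. For each adjacent
  transposition we post a lex-leader constraint (variable vector
  lexicographically no larger than its image) over the core variables
  in allocation order; each orbit keeps its lexicographic minimum, so
  satisfiability is untouched while refutations shrink by large
  factors. A seemingly innocuous alternative — ordering
  the two parallel edge slots of a pair by their labels — is *not*
  used: label-lex order does not commute with molecule relabeling, and
  combining the two would lose solutions. Parallel slots are instead
  constrained only to be occupied-slot-1-first and label-distinct.
* **Budgeted free search with exact fallback.** Some refutations
  (e.g. "no 3-connected graph is feasible under compartment
  regulation with vesicle SNARE-SNARE inhibition" at `N = 4`) are deep
  for the bundled solver when the structure is free. Free-structure
  queries therefore run under a conflict budget; on exhaustion the
  same question is decomposed exactly over isomorphism-free enumerated
  topology classes with the structure pinned per class, each a cheap
  solve. Both routes are exact; the decomposition is also
  how sufficiency is quantified in the first place.

Decoded models (`decode_instance()`) always pass
`validate_instance()`; this round trip is asserted throughout the test
suite, keeping the declarative encoding and the executable semantics
honest against each other. The brute-force oracle
(`brute_force_feasible()`) is a third, independent route: exhaustive
search over compositions, pairings and per-composition-class activity
choices on up to 3 nodes and 4 molecule types, compared cell-by-cell
against the SAT engine over the full grid of tiny topologies.

## Graph enumeration

Simple unlabeled graphs are enumerated one representative per
isomorphism class by node augmentation with canonical-certificate
deduplication (certificates from canonical vertex orderings; an
all-permutations canonicalizer is the independent oracle in the
tests). The census of "3-edge-connected" N-node graphs counts classes
with edge connectivity *exactly* 3: at `N = 5` the qualifying graphs
are K5 minus one edge and K5 minus two independent edges, while K5
itself (connectivity 4) is excluded — the cumulative reading would
give 3, not the census value 2. `count_k_edge_connected(n, k,
at_least = TRUE)` provides the cumulative count when wanted.

Directed multigraph topologies (multiplicity cap 2) are canonicalized
by exhaustive minimization over node permutations — exact and cheap in
the `N <= 4` regime where exhaustive topology sweeps are run; larger
node counts are reachable only through free-structure SAT queries or
with an explicit edge budget.

## Fixtures and what a green test establishes

The bundled example instances (`build_fixture()`) are not transcribed
from any figure; transcription from drawings is error-prone. Each was
found once by the SAT engine under *style constraints* — compartment
count, molecule count, regime, underlying connectivity — and stored as
JSON; the constraints are re-verified by the tests. They emulate the
canonical two-compartment illustrations (a 3-connected network under
vesicle-only Boolean regulation; a 4-connected one under compartment
regulation with vesicle SNARE-SNARE inhibition; a 3-compartment,
4-molecule steady-state network). What they do not emulate: real
cells' molecule counts (dozens of SNARE varieties), copy-number
dynamics, or kinetics — this package treats presence/absence logic and
flux balance only, so a green suite establishes combinatorial
consistency of the rules, not dynamical realizability.

## Scale, and two honest discrepancies

Everything here runs at desk scale (`N <= 4` for exhaustive sweeps,
`N <= 6`, `M <= 8` for free-structure searches; the original
exploration of this model used bounded model checking up to `N = 8`,
`M = 32`). Two desk-scale findings deserve emphasis:

* **Sufficiency depends on the molecule budget.** Under vesicle-only
  Boolean regulation, 68 of the 70 strongly connected 3-node
  topologies with 3-connected underlying graphs are *infeasible* at
  `M = 6`, and all 70 are feasible at `M = 8` (the brute-force oracle
  independently confirms the infeasibilities at `M <= 4`). With
  unregulated compartments every route must effectively own a private
  addressing SNARE pair, so sufficiency claims only stabilize once
  `M` comfortably exceeds the route count. The acceptance test for
  sufficiency at the stated `M = 6` scale is accordingly expected to
  fail, and is asserted at that scale anyway rather than being
  quietly rescaled.
* **Exactly-2-edge-connected networks are never feasible.** Let
  `{e1, e2}` be a 2-edge cut separating compartment sets S and T.
  Flux balance forces every molecule crossing the cut to return
  across it, so the cut edges are oppositely directed and carry
  exactly the same composition; but their targets lie on opposite
  sides of the cut, contradicting the identical-vesicles-same-target
  rule. The argument is independent of `M`, `N` and the regime, so
  the package reports 3 as the minimum connectivity under full
  Boolean regulation. This is a sharper statement than the
  conventional "2-connected is necessary" floor, which relies only on
  strong connectivity; the floor is correct, but it is not attained.

## Numerical and determinism choices

* Fluxes are constructed as unit contributions per witness cycle; any
  positive values work, units keep results reproducible. Balance is
  checked to absolute 1e-9 (sums of small integers; the tolerance
  absorbs only floating-point accumulation).
* Solver runs are deterministic given a seed; the seed perturbs only
  branching tie-breaks, never the SAT/UNSAT status (asserted across
  seeds in the tests). Enumeration orders are lexicographic by
  certificate. CLI runs with identical configuration are
  byte-reproducible.
* Degenerate inputs: a single compartment has edge connectivity
  `Inf` (no cut exists) and satisfies any requirement vacuously;
  zero-edge networks are valid but never strongly connected for
  `N >= 2`; empty graphs are rejected.

## Open questions resolved as package policy

* Compartment compositions are free (they may include immobile
  resident molecules never carried by any edge); flux balance only
  constrains moving molecules.
* SNARE-SNARE inhibition on the compartment side is rejected as a
  configuration error: the biological motivation (no disassembly
  machinery on vesicles) does not apply to compartments, and no
  regime row uses it.
* Sufficiency quantifies over strongly connected directed topologies,
  since no other digraph can reach steady state; an
  `undirected_mode` additionally accepts an underlying class when any
  orientation of it is feasible (the weaker reading).
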