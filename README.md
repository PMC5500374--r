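# snaresat

SNARE-regulated vesicle traffic networks as a Boolean satisfiability
problem.

## The problem

A eukaryotic cell is a set of membrane-bound compartments exchanging
cargo through vesicles: each compartment is a node of a directed
multigraph, each vesicle route a directed edge, and every membrane is
labeled by the subset of *M* molecular types it carries (Q-SNAREs in
the first half of the index space, R-SNAREs in the second). Fusion of
a vesicle with a compartment requires one *active* Q–R SNARE pair
drawn from an *M* × *M* binary pairing matrix; SNARE activity may be
regulated by the other molecules on the same membrane; and at steady
state every molecule leaving a compartment must return to it along a
cycle of molecule-carrying routes.

Which transport graphs can such a system realize? Writing λ(G) for the
edge connectivity of the underlying undirected multigraph, the
question splits per regulation regime *R* into

* **necessity** — the least λ over all feasible (graph, labels,
  pairing, regulation) instances, and
* **sufficiency** — the least k such that *every* strongly connected
  graph with λ ≥ k admits a feasible labeling,

both decided exhaustively within finite bounds (node count N,
molecule count M, per-pair edge multiplicity ≤ 2) by reducing
feasibility — steady state (C1), fusion rules (C2), topology respect
(C3), connectivity class (C4) — to CNF-SAT and solving with a bundled
CDCL solver. A brute-force oracle and executable model semantics
provide two independent routes against which every SAT verdict is
cross-checked. The package is aimed at systems biologists and
formal-methods people studying membrane-traffic organization.

## Worked example

Find a two-compartment, six-molecule steady-state network with
3-edge-connected underlying graph when compartments are unregulated
and vesicle SNAREs carry Boolean regulation; then validate it and
assign fluxes:

```r
library(snaresat)

b   <- search_bounds(2, 6, strongly_connected_only = TRUE,
                     connectivity = list(type = "exact", k = 3L))
enc <- encode_feasibility(b, regime_row(2), nodes = 2)
v   <- solve_cnf(enc$cnf, seed = 0)
inst <- decode_instance(v, enc)
inst
#> Regulation regime: compartment = none | vesicle = boolean
#> Transport network: 2 compartments, 3 vesicle edges, M = 6
#>   node n1     [111 110]
#>   node n2     [111 101]
#>   edge n1 -> n2 [111 100]
#>   edge n2 -> n1 [110 100]
#>   edge n2 -> n1 [111 000]

validate_instance(inst)
#> Instance validation: PASS
#>   structural:        PASS
#>   C1 steady state:   PASS
#>   C2 fusion rules:   PASS
#>   C3 topology:       PASS

edge_connectivity(underlying_multigraph(inst$network))
#> [1] 3
assign_fluxes(inst$network)   # row = edge, column = molecule; balanced per node
#>      [,1] [,2] [,3] [,4] [,5] [,6]
#> [1,]    2    3    3    0    0    2
#> [2,]    0    2    2    0    0    2
#> [3,]    2    1    1    0    0    0
```

Node labels print Q-block then R-block, highest index first: `n1`'s
`[111 110]` carries Q2 Q1 Q0 and R2 R1 but not R0. Each edge's flux
column sums balance at both nodes (1 unit per cycle witness), and
every carried molecule is positive on its edges.

The regime table itself, at desk scale:

```r
min_feasible_connectivity(regime_row(2), search_bounds(4, 6))  # none/boolean
#> [1] 3
min_feasible_connectivity(regime_row(3), search_bounds(4, 6))  # boolean/inhibition
#> [1] 4
min_feasible_connectivity(regime_row(6), search_bounds(3, 6))  # none/none
#> NULL   (no feasible network at all)
count_k_edge_connected(6, 3)   # simple 6-node graphs, edge connectivity 3
#> [1] 15
```

A command-line surface wraps the same workflows
(`?snaresat_cli`): `validate`, `fluxes`, `table2`, `enumerate`,
`find`, `necessity`, `sufficiency`, `oracle`, `fixture`, `export`
(DOT/GraphML/DIMACS/JSON).

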