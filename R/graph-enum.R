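# Isomorphism-free enumeration of candidate topologies: simple
# undirected graphs (for the 3-edge-connected census) and bounded
# directed multigraphs (for feasibility and sufficiency sweeps).

#' Canonical certificate of a simple undirected graph
#'
#' Certificates are equal iff the graphs are isomorphic. Computed via
#' canonical vertex ordering (McKay-style refinement/backtracking as
#' implemented by igraph's BLISS); a brute-force all-permutations
#' canonicalizer serves as the independent test oracle for small n.
#'
#' @param n node count.
#' @param edges 2-column integer matrix of undirected edges (may have
#'   zero rows).
#' @return `vt_canonical_graph`: list(n, edges, certificate).
#' @export
canonical_graph <- function(n, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) == 0) {
    return(structure(list(n = n, edges = edges,
                          certificate = paste0(n, ":")),
                     class = "vt_canonical_graph"))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  perm <- igraph::canonical_permutation(g)$labeling
  ce <- cbind(perm[edges[, 1]], perm[edges[, 2]])
  ce <- t(apply(ce, 1, sort))
  ce <- ce[order(ce[, 1], ce[, 2]), , drop = FALSE]
  structure(list(n = n, edges = ce,
                 certificate = paste0(n, ":", paste(ce[, 1], ce[, 2],
                                                    sep = "-", collapse = ","))),
            class = "vt_canonical_graph")
}

# all-permutations canonical certificate: the independent oracle
# (exact but factorial; used in tests for n <= 5)
canonical_graph_bruteforce <- function(n, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) == 0) return(paste0(n, ":"))
  perms <- all_permutations(n)
  best <- NULL
  for (p in perms) {
    ce <- cbind(p[edges[, 1]], p[edges[, 2]])
    ce <- t(apply(ce, 1, sort))
    ce <- ce[order(ce[, 1], ce[, 2]), , drop = FALSE]
    s <- paste(ce[, 1], ce[, 2], sep = "-", collapse = ",")
    if (is.null(best) || s < best) best <- s
  }
  paste0(n, ":", best)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

# one level of node augmentation with certificate dedup: every simple
# graph on n nodes arises from a graph on n-1 nodes (delete node n) by
# attaching a new node to some neighbor subset
enum_simple_level <- function(prev, n) {
  seen <- new.env(parent = emptyenv())
  out <- list()
  subsets <- 0:(2^(n - 1) - 1)
  bitvals <- 2^(seq_len(n - 1) - 1)
  for (g in prev) {
    for (mask in subsets) {
      nbrs <- which(bitwAnd(mask, bitvals) > 0)
      edges <- rbind(g$edges,
                     if (length(nbrs)) cbind(nbrs, n) else NULL)
      cg <- canonical_graph(n, edges)
      if (!exists(cg$certificate, envir = seen)) {
        assign(cg$certificate, TRUE, envir = seen)
        out[[length(out) + 1L]] <- cg
      }
    }
  }
  out[order(vapply(out, `[[`, "", "certificate"))]
}

#' Enumerate simple undirected graphs up to isomorphism
#'
#' Exactly one representative per isomorphism class, generated by node
#' augmentation with canonical-certificate deduplication; deterministic
#' (lexicographic by certificate). Levels are cached per session.
#'
#' @param n node count, 1..9 (practical bound).
#' @param connected_only keep only connected graphs.
#' @return list of `vt_canonical_graph`.
#' @export
enumerate_simple_graphs <- function(n, connected_only = FALSE) {
  if (!is.numeric(n) || n < 1 || n > 9)
    stop("simple-graph enumeration supports 1 <= n <= 9")
  n <- as.integer(n)
  key <- paste0("simple", n)
  if (is.null(.snaresat_cache[[key]])) {
    if (n == 1) {
      .snaresat_cache[[key]] <- list(canonical_graph(1L, matrix(0L, 0, 2)))
    } else {
      prev <- enumerate_simple_graphs(n - 1L)
      .snaresat_cache[[key]] <- enum_simple_level(prev, n)
    }
  }
  out <- .snaresat_cache[[key]]
  if (connected_only) {
    keep <- vapply(out, function(g) {
      if (g$n == 1) return(TRUE)
      if (nrow(g$edges) < g$n - 1) return(FALSE)
      ig <- igraph::make_empty_graph(g$n, directed = FALSE)
      ig <- igraph::add_edges(ig, t(g$edges))
      igraph::is_connected(ig)
    }, logical(1))
    out <- out[keep]
  }
  out
}

# fast subset-cut edge connectivity for a simple graph given as an
# adjacency matrix; masks precomputed by caller
simple_edge_connectivity <- function(A, submasks) {
  n <- nrow(A)
  best <- Inf
  for (r in seq_len(nrow(submasks))) {
    s <- submasks[r, ]
    cut <- sum(A[s, !s, drop = FALSE])
    if (cut < best) best <- cut
  }
  best
}

#' Count k-edge-connected simple graph classes
#'
#' Number of isomorphism classes of simple undirected n-node graphs
#' whose edge connectivity is exactly k. This is the census's reading
#' of "k-edge-connected": at 5 nodes the exactly-3 classes are K5
#' minus one edge and K5 minus a 2-edge matching (count 2), while K5
#' itself (connectivity 4) is counted under k = 4. Set `at_least =
#' TRUE` for the cumulative reading (connectivity >= k).
#'
#' @param n node count.
#' @param k connectivity level.
#' @param at_least count connectivity >= k instead of == k.
#' @return integer count.
#' @export
count_k_edge_connected <- function(n, k, at_least = FALSE) {
  graphs <- enumerate_simple_graphs(n)
  if (n == 1) return(0L)   # single node: no cut exists
  submasks <- matrix(FALSE, 2^(n - 1) - 1, n)
  for (mask in 0:(2^(n - 1) - 2))
    submasks[mask + 1L, ] <- c(TRUE, bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0)
  cnt <- 0L
  for (g in graphs) {
    if (nrow(g$edges) < ceiling(k * n / 2)) next   # degree bound
    A <- matrix(0L, n, n)
    A[g$edges] <- 1L
    A <- A + t(A)
    if (min(rowSums(A)) < k) next                  # lambda <= min degree
    lambda <- simple_edge_connectivity(A, submasks)
    if (if (at_least) lambda >= k else lambda == k) cnt <- cnt + 1L
  }
  cnt
}

#' Census of 3-edge-connected graph classes
#'
#' The two-column table "nodes N / number of simple 3-edge-connected
#' unlabeled N-node graphs" for N = 1..max_nodes.
#'
#' @param max_nodes largest node count (<= 9 practical).
#' @return data.frame with columns `N` and `count`.
#' @export
table_three_connected <- function(max_nodes = 8) {
  data.frame(N = seq_len(max_nodes),
             count = vapply(seq_len(max_nodes), count_k_edge_connected,
                            integer(1), k = 3L))
}

#' Search bounds
#'
#' The finite search space for feasibility questions: node count,
#' molecule count, per-ordered-pair multiplicity cap, optional total
#' edge budget, optional connectivity requirement, and whether only
#' strongly connected topologies are considered.
#'
#' @param max_nodes maximum number of compartments.
#' @param molecules even number M of molecular types.
#' @param max_multiplicity per-ordered-pair edge cap (default 2).
#' @param edge_budget optional maximum total edge count.
#' @param connectivity optional list(type, k) with type one of
#'   `"geq"`, `"exact"`, `"below"`.
#' @param strongly_connected_only restrict to strongly connected
#'   topologies.
#' @return `vt_bounds` list.
#' @export
search_bounds <- function(max_nodes, molecules, max_multiplicity = 2,
                          edge_budget = NULL, connectivity = NULL,
                          strongly_connected_only = FALSE) {
  if (molecules %% 2 != 0) stop("molecules must be even")
  if (max_multiplicity < 1) stop("max_multiplicity must be >= 1")
  structure(list(max_nodes = as.integer(max_nodes),
                 molecules = as.integer(molecules),
                 max_multiplicity = as.integer(max_multiplicity),
                 edge_budget = edge_budget,
                 connectivity = connectivity,
                 strongly_connected_only = strongly_connected_only),
            class = "vt_bounds")
}

#' Enumerate directed multigraph topologies up to isomorphism
#'
#' One representative per isomorphism class of directed multigraphs on
#' exactly `nodes` nodes with per-ordered-pair multiplicity at most
#' `bounds$max_multiplicity`, optionally filtered to strongly connected
#' topologies and/or by the edge connectivity of the underlying
#' undirected multigraph. Canonical forms are lexicographic minima over
#' all node permutations (exact); deterministic certificate order.
#'
#' @param bounds a [search_bounds()].
#' @param nodes exact node count (default `bounds$max_nodes`).
#' @return list of `vt_topology`: list(n, mult, certificate,
#'   connectivity, strong).
#' @export
enumerate_topologies <- function(bounds, nodes = bounds$max_nodes) {
  n <- as.integer(nodes)
  budget <- if (is.null(bounds$edge_budget)) -1L else as.integer(bounds$edge_budget)
  raw <- .topo_enum_cpp(n, bounds$max_multiplicity, budget)
  out <- list()
  for (i in seq_along(raw$matrices)) {
    strong <- raw$strong[i] == 1L
    if (bounds$strongly_connected_only && !strong) next
    conn <- raw$connectivity[i]
    conn <- if (is.na(conn)) Inf else conn
    if (!is.null(bounds$connectivity)) {
      k <- bounds$connectivity$k
      keep <- switch(bounds$connectivity$type,
                     geq = conn >= k,
                     exact = conn == k,
                     below = conn < k,
                     stop("unknown connectivity type"))
      if (!keep) next
    }
    out[[length(out) + 1L]] <-
      structure(list(n = n, mult = raw$matrices[[i]],
                     certificate = raw$certificate[i],
                     connectivity = conn, strong = strong),
                class = "vt_topology")
  }
  out
}

#' @export
print.vt_topology <- function(x, ...) {
  cat(sprintf("Topology on %d nodes (underlying connectivity %s%s)\n",
              x$n, x$connectivity, if (x$strong) ", strongly connected" else ""))
  print(x$mult)
  invisible(x)
}
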