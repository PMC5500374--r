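# Connectivity analysis: strong connectivity of the directed
# multigraph, and k-edge-connectivity of the underlying undirected
# multigraph (parallel edges count individually in cuts).

#' Underlying undirected multigraph
#'
#' Collapses a transport network's directed multigraph onto node pairs:
#' the multiplicity of the unordered pair \{u,v\} is the number of
#' directed edges u->v plus the number v->u.
#'
#' @param network a [transport_network()], or a square multiplicity
#'   matrix of a directed multigraph.
#' @return `vt_umg`: list with `nodes` and symmetric integer
#'   multiplicity matrix `mult` (zero diagonal).
#' @export
underlying_multigraph <- function(network) {
  if (inherits(network, "vt_network")) {
    ids <- network$node_ids
    n <- length(ids)
    m <- matrix(0L, n, n, dimnames = list(ids, ids))
    for (i in seq_along(network$edge_src))
      m[network$edge_src[i], network$edge_tgt[i]] <-
        m[network$edge_src[i], network$edge_tgt[i]] + 1L
  } else {
    m <- as.matrix(network)
    ids <- rownames(m)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
    dimnames(m) <- list(ids, ids)
  }
  und <- m + t(m)
  diag(und) <- 0L
  structure(list(nodes = ids, mult = und), class = "vt_umg")
}

#' Edge connectivity of an undirected multigraph
#'
#' The minimum number of edges whose removal disconnects the graph
#' (parallel edges count individually); 0 for a disconnected graph and
#' `Inf` for a single node (no cut exists). Two independent methods
#' are provided and must agree: exhaustive enumeration of node-subset
#' cuts (exact, up to 8 nodes) and repeated max-flow/min-cut.
#'
#' @param g a `vt_umg` from [underlying_multigraph()] (or an object
#'   coercible by it).
#' @param method `"subset"`, `"maxflow"` or `"auto"`.
#' @return non-negative number (possibly `Inf`).
#' @export
edge_connectivity <- function(g, method = c("auto", "subset", "maxflow")) {
  method <- match.arg(method)
  if (!inherits(g, "vt_umg")) g <- underlying_multigraph(g)
  n <- length(g$nodes)
  if (n == 0) stop("edge connectivity is undefined for the empty graph")
  if (n == 1) return(Inf)
  if (method == "auto") method <- if (n <= 8) "subset" else "maxflow"
  if (method == "subset") {
    if (n > 8) stop("subset enumeration supports at most 8 nodes")
    best <- Inf
    for (mask in 0:(2^(n - 1) - 2)) {
      inS <- c(TRUE, as.logical(bitwAnd(mask, 2^(seq_len(n - 1) - 1))))
      cut <- sum(g$mult[inS, !inS, drop = FALSE])
      if (cut < best) best <- cut
    }
    return(best)
  }
  # max-flow: lambda = min over t != s of maxflow(s, t) on the
  # unit-capacity expansion of the multigraph
  el <- NULL
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    k <- g$mult[i, j]
    if (k > 0) el <- rbind(el, matrix(rep(c(i, j), k), ncol = 2, byrow = TRUE))
  }
  if (is.null(el)) return(0)
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, n - igraph::vcount(ig)))
  if (igraph::components(ig)$no > 1) return(0)
  best <- Inf
  for (t in seq.int(2, n))
    best <- min(best, igraph::max_flow(
      ig, source = 1, target = t,
      capacity = rep(1, igraph::ecount(ig)))$value)
  best
}

#' Strong connectivity of a transport network
#'
#' TRUE iff there is a directed path from every compartment to every
#' other compartment. Steady state over a single component requires
#' strong connectivity, which in turn forces the underlying multigraph
#' to be at least 2-edge-connected.
#'
#' @param network a [transport_network()] or a multiplicity matrix.
#' @return logical.
#' @export
is_strongly_connected <- function(network) {
  if (inherits(network, "vt_network")) {
    n <- length(network$node_ids)
    if (n == 1) return(TRUE)
    if (!length(network$edge_src)) return(FALSE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = network$edge_src, to = network$edge_tgt),
      directed = TRUE, vertices = data.frame(name = network$node_ids))
  } else {
    m <- as.matrix(network)
    n <- nrow(m)
    if (n == 1) return(TRUE)
    g <- igraph::graph_from_adjacency_matrix(pmin(m, 1L), mode = "directed")
  }
  igraph::is_connected(g, mode = "strong")
}

#' Connectivity classification relative to k
#'
#' Classifies a graph's edge connectivity lambda against a target k:
#' `"at_least_k"` (lambda >= k), `"between_k_minus_1_and_k"`
#' (lambda = k-1), or `"below_k_minus_1"`.
#'
#' @param g as in [edge_connectivity()].
#' @param k integer >= 1.
#' @return character classification.
#' @export
connectivity_class <- function(g, k) {
  if (k < 1) stop("k must be >= 1")
  lambda <- edge_connectivity(g)
  if (lambda >= k) "at_least_k"
  else if (lambda == k - 1) "between_k_minus_1_and_k"
  else "below_k_minus_1"
}
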