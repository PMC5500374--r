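# Domain types of the RSS vesicle-traffic model: molecule universe,
# compositions, compartments, vesicle edges, transport networks,
# pairing matrices, regulation regimes and regimes' Boolean functions.

#' Molecule universe
#'
#' Defines the set of molecular types. `M` must be even: indices
#' `1..M/2` are Q-SNAREs, `M/2+1..M` are R-SNAREs (1-based). Molecules
#' that never appear in the pairing matrix act as pure regulators.
#'
#' @param M positive even integer, number of molecular types.
#' @return An object of class `vt_universe` with fields `M`,
#'   `q_indices`, `r_indices`.
#' @examples
#' u <- molecule_universe(6)
#' u$q_indices  # 1 2 3
#' @export
molecule_universe <- function(M) {
  if (!is.numeric(M) || length(M) != 1 || M < 2 || M %% 2 != 0)
    stop("M must be a positive even integer >= 2")
  M <- as.integer(M)
  structure(list(M = M,
                 q_indices = seq_len(M %/% 2),
                 r_indices = seq.int(M %/% 2 + 1L, M)),
            class = "vt_universe")
}

#' @export
print.vt_universe <- function(x, ...) {
  cat("Molecule universe: M =", x$M,
      sprintf("(%d Q-SNAREs, %d R-SNAREs)\n", length(x$q_indices),
              length(x$r_indices)))
  invisible(x)
}

#' Compositions
#'
#' A composition is the 0/1 presence vector of the M molecular types on
#' a membrane. The printed form follows the bracket convention of the
#' model's figures: Q-block then R-block, each block written from the
#' highest molecule index down to the lowest, e.g. with M = 6 the
#' string `"101 100"` carries Q2, Q0 and R2 (1-based indices 3, 1, 6).
#'
#' @param x 0/1 vector of length M, or a character vector of molecule
#'   labels such as `"Q0"`, `"R2"`.
#' @param universe a [molecule_universe()].
#' @return integer 0/1 vector of length M.
#' @export
composition <- function(x, universe) {
  M <- universe$M
  if (is.character(x)) {
    v <- integer(M)
    for (lab in x) {
      cls <- toupper(substr(lab, 1, 1))
      idx <- suppressWarnings(as.integer(substr(lab, 2, nchar(lab))))
      if (is.na(idx) || !cls %in% c("Q", "R") || idx >= M %/% 2 || idx < 0)
        stop("bad molecule label: ", lab)
    v[if (cls == "Q") idx + 1L else M %/% 2 + idx + 1L] <- 1L
    }
    return(v)
  }
  if (length(x) != M) stop("composition must have length M = ", M)
  if (!all(x %in% c(0, 1))) stop("composition must be a 0/1 vector")
  as.integer(x)
}

#' @rdname composition
#' @param comp integer 0/1 composition vector.
#' @param space use a space between the Q and R blocks (default TRUE).
#' @export
comp_to_string <- function(comp, space = TRUE) {
  M <- length(comp)
  h <- M %/% 2
  q <- paste(rev(comp[seq_len(h)]), collapse = "")
  r <- paste(rev(comp[seq.int(h + 1L, M)]), collapse = "")
  if (space) paste(q, r) else paste0(q, r)
}

#' @rdname composition
#' @param s composition string, Q-block then R-block, optional space.
#' @param M number of molecular types.
#' @export
comp_from_string <- function(s, M) {
  digits <- strsplit(gsub("[^01]", "", s), "")[[1]]
  if (length(digits) != M)
    stop("composition string '", s, "' does not have ", M, " binary digits")
  h <- M %/% 2
  bits <- as.integer(digits)
  c(rev(bits[seq_len(h)]), rev(bits[seq.int(h + 1L, M)]))
}

#' Compartment and vesicle edge constructors
#'
#' A compartment is a node of the transport graph with a composition; a
#' vesicle edge carries a non-empty composition from a source to a
#' distinct target compartment, and may carry only molecules present on
#' its source.
#'
#' @param id character node identifier.
#' @param comp composition vector (see [composition()]).
#' @return a `vt_compartment` / `vt_edge` list.
#' @export
compartment <- function(id, comp) {
  structure(list(id = as.character(id), composition = as.integer(comp)),
            class = "vt_compartment")
}

#' @rdname compartment
#' @param source,target compartment ids.
#' @export
vesicle_edge <- function(source, target, comp) {
  structure(list(source = as.character(source), target = as.character(target),
                 composition = as.integer(comp)),
            class = "vt_edge")
}

#' Transport network
#'
#' The directed multigraph of compartments and vesicle routes. Structural
#' invariants (checked unless `check = FALSE`): no self edges, at most
#' two edges per ordered node pair, parallel same-direction edges carry
#' distinct compositions, every edge composition is non-empty and a
#' subset of its source compartment's composition.
#'
#' @param universe a [molecule_universe()].
#' @param compartments list of [compartment()] objects, or a named list
#'   of composition vectors.
#' @param edges list of [vesicle_edge()] objects (may be empty).
#' @param check validate structural invariants (default TRUE).
#' @return `vt_network`: list with `universe`, `node_ids`, `node_comp`
#'   (n x M matrix, rownames = ids), `edge_src`, `edge_tgt`,
#'   `edge_comp` (E x M matrix).
#' @export
transport_network <- function(universe, compartments, edges = list(),
                              check = TRUE) {
  M <- universe$M
  if (length(compartments) == 0) stop("a network needs at least one compartment")
  if (inherits(compartments[[1]], "vt_compartment")) {
    ids <- vapply(compartments, `[[`, "", "id")
    comps <- lapply(compartments, `[[`, "composition")
  } else {
    ids <- names(compartments)
    comps <- compartments
  }
  if (is.null(ids) || anyNA(ids)) stop("compartments must be named")
  node_comp <- do.call(rbind, lapply(comps, as.integer))
  rownames(node_comp) <- ids

  E <- length(edges)
  edge_src <- character(E); edge_tgt <- character(E)
  edge_comp <- matrix(0L, E, M)
  for (i in seq_len(E)) {
    e <- edges[[i]]
    edge_src[i] <- e$source; edge_tgt[i] <- e$target
    edge_comp[i, ] <- as.integer(e$composition)
  }
  net <- structure(list(universe = universe, node_ids = ids,
                        node_comp = node_comp, edge_src = edge_src,
                        edge_tgt = edge_tgt, edge_comp = edge_comp),
                   class = "vt_network")
  if (check) {
    v <- network_structural_violations(net)
    if (length(v)) stop("invalid transport network:\n  ",
                        paste(v, collapse = "\n  "))
  }
  net
}

# structural invariant findings (character vector, empty when valid)
network_structural_violations <- function(net) {
  out <- character()
  M <- net$universe$M
  ids <- net$node_ids
  if (anyDuplicated(ids)) out <- c(out, "duplicate compartment ids")
  if (ncol(net$node_comp) != M) out <- c(out, "node composition width != M")
  E <- length(net$edge_src)
  if (E == 0) return(out)
  bad_ref <- !(net$edge_src %in% ids) | !(net$edge_tgt %in% ids)
  if (any(bad_ref))
    out <- c(out, paste0("edge ", which(bad_ref), " references unknown node"))
  self <- net$edge_src == net$edge_tgt
  if (any(self))
    out <- c(out, paste0("edge ", which(self), " is a self edge"))
  empty <- rowSums(net$edge_comp) == 0
  if (any(empty))
    out <- c(out, paste0("edge ", which(empty), " has empty composition"))
  for (i in seq_len(E)) {
    if (net$edge_src[i] %in% ids) {
      src <- net$node_comp[net$edge_src[i], ]
      if (any(net$edge_comp[i, ] > src))
        out <- c(out, paste0("edge ", i, " (", net$edge_src[i], "->",
                             net$edge_tgt[i],
                             ") carries molecules absent from its source"))
    }
  }
  key <- paste(net$edge_src, net$edge_tgt)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) > 2)
      out <- c(out, paste0("more than 2 parallel edges for pair ", k))
    if (length(idx) >= 2) {
      labs <- apply(net$edge_comp[idx, , drop = FALSE], 1, paste, collapse = "")
      if (anyDuplicated(labs))
        out <- c(out, paste0("identical parallel edge compositions for pair ", k))
    }
  }
  out
}

#' @export
print.vt_network <- function(x, ...) {
  cat(sprintf("Transport network: %d compartments, %d vesicle edges, M = %d\n",
              length(x$node_ids), length(x$edge_src), x$universe$M))
  for (i in seq_along(x$node_ids))
    cat(sprintf("  node %-6s [%s]\n", x$node_ids[i],
                comp_to_string(x$node_comp[i, ])))
  for (i in seq_along(x$edge_src))
    cat(sprintf("  edge %s -> %s [%s]\n", x$edge_src[i], x$edge_tgt[i],
                comp_to_string(x$edge_comp[i, ])))
  invisible(x)
}

#' SNARE pairing matrix
#'
#' M x M binary table; rows index the SNARE on the vesicle membrane,
#' columns the SNARE on the compartment membrane. A non-zero entry marks
#' a fusion-competent pair. Entries are only permitted for Q-R or R-Q
#' combinations; the matrix need not be symmetric (vesicle and
#' compartment surfaces differ physically).
#'
#' @param entries M x M 0/1 matrix.
#' @param universe a [molecule_universe()].
#' @return `vt_pairing` (the matrix with the universe attached).
#' @export
pairing_matrix <- function(entries, universe) {
  M <- universe$M
  entries <- matrix(as.integer(entries), M, M)
  if (!all(entries %in% c(0L, 1L))) stop("pairing entries must be 0/1")
  qi <- universe$q_indices; ri <- universe$r_indices
  if (any(entries[qi, qi] != 0) || any(entries[ri, ri] != 0))
    stop("pairing entries are only allowed for Q-R or R-Q combinations")
  structure(entries, universe = universe, class = c("vt_pairing", "matrix"))
}

#' Regulation regimes
#'
#' The six regimes pair a compartment-side rule (`"none"` or
#' `"boolean"`) with a vesicle-side rule (`"none"`, `"boolean"` or
#' `"snare_inhibition"`). Under `"none"` every present molecule is
#' active; under `"boolean"` activity is an arbitrary Boolean function
#' of the membrane's composition (one function per molecule per side,
#' applied cell-wide); under SNARE-SNARE inhibition a molecule is
#' inactivated by the presence, on the same vesicle, of any partner in
#' either orientation of the pairing matrix (NSF is absent from
#' vesicles, so zipped pairs stay locked). SNARE-SNARE inhibition is a
#' vesicle-side rule only.
#'
#' @param compartment one of `"none"`, `"boolean"`.
#' @param vesicle one of `"none"`, `"boolean"`, `"snare_inhibition"`.
#' @return `vt_regime` list.
#' @export
regulation_regime <- function(compartment = "none", vesicle = "none") {
  compartment <- match.arg(compartment, c("none", "boolean"))
  vesicle <- match.arg(vesicle, c("none", "boolean", "snare_inhibition"))
  structure(list(compartment_rule = compartment, vesicle_rule = vesicle),
            class = "vt_regime")
}

#' @rdname regulation_regime
#' @param row integer 1..6, the standard ordering of the regime table:
#'   1 = boolean/boolean, 2 = none/boolean, 3 = boolean/snare_inhibition,
#'   4 = none/snare_inhibition, 5 = boolean/none, 6 = none/none.
#' @export
regime_row <- function(row) {
  tab <- list(c("boolean", "boolean"),
              c("none", "boolean"),
              c("boolean", "snare_inhibition"),
              c("none", "snare_inhibition"),
              c("boolean", "none"),
              c("none", "none"))
  if (!row %in% 1:6) stop("regime row must be in 1..6")
  r <- tab[[row]]
  regulation_regime(r[1], r[2])
}

#' @export
print.vt_regime <- function(x, ...) {
  cat("Regulation regime: compartment =", x$compartment_rule,
      "| vesicle =", x$vesicle_rule, "\n")
  invisible(x)
}

#' Explicit regulation functions
#'
#' For Boolean regulation, the activity of each molecule is a function
#' of the full membrane composition, identical for all membranes of the
#' same side (functional consistency). Represented extensionally: per
#' side, a named character vector mapping composition strings (no
#' space) to activity strings; compositions not listed default to
#' all-inactive. Activity is clipped to presence: a molecule absent
#' from a composition is never active.
#'
#' @param compartment,vesicle named character vectors (may be NULL when
#'   the side's rule is not `"boolean"`).
#' @return `vt_regulation` list.
#' @export
regulation_function <- function(compartment = NULL, vesicle = NULL) {
  structure(list(compartment = compartment, vesicle = vesicle),
            class = "vt_regulation")
}

#' Network instance
#'
#' A candidate steady-state traffic network: transport graph plus
#' pairing matrix, regulation regime, and (for Boolean rules) the
#' explicit regulation functions.
#'
#' @param network a [transport_network()].
#' @param pairing a [pairing_matrix()].
#' @param regime a [regulation_regime()].
#' @param regulation a [regulation_function()], required iff either
#'   side's rule is `"boolean"`.
#' @return `vt_instance` list.
#' @export
network_instance <- function(network, pairing, regime, regulation = NULL) {
  structure(list(network = network, pairing = pairing, regime = regime,
                 regulation = regulation),
            class = "vt_instance")
}

#' @export
print.vt_instance <- function(x, ...) {
  print(x$regime)
  print(x$network)
  invisible(x)
}
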