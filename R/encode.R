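# CNF encoding of bounded feasibility: satisfying assignments are
# exactly the valid network instances (structure, compositions,
# regulation, fusion rules C2/C3, steady state C1, optional
# connectivity class) within the given bounds. Replaces the original
# bounded-model-checking pipeline with direct clause generation.

#' Encode bounded feasibility as CNF
#'
#' Builds a propositional formula whose models are the valid
#' steady-state traffic networks on exactly `nodes` compartments with
#' `bounds$molecules` molecular types, under the given regulation
#' regime. Structure variables (edge slots) are free unless
#' `fixed_topology` is supplied, in which case they are pinned by unit
#' clauses. Boolean regulation is encoded with free activity variables
#' constrained by functional consistency (equal compositions on the
#' same side force equal activity), not by truth tables. Steady state
#' uses step-indexed reachability with biconditional definitions
#' unrolled to N-1 steps; connectivity classes use subset-crossing
#' cardinality constraints (sequential counters), exact for N <= 8.
#'
#' @param bounds a [search_bounds()]; `bounds$connectivity` (list(type,
#'   k) with type `"geq"`, `"exact"` or `"below"`) adds the C4-style
#'   constraint, `bounds$strongly_connected_only` adds directed cut
#'   clauses, `bounds$edge_budget` caps the total edge count.
#' @param regime a [regulation_regime()].
#' @param fixed_topology optional n x n multiplicity matrix.
#' @param nodes exact compartment count (default: the fixed topology's,
#'   else `bounds$max_nodes`).
#' @return `vt_encoding`: list(cnf, varmap, bounds, regime).
#' @export
encode_feasibility <- function(bounds, regime, fixed_topology = NULL,
                               nodes = NULL) {
  n <- if (!is.null(nodes)) as.integer(nodes)
       else if (!is.null(fixed_topology)) nrow(fixed_topology)
       else bounds$max_nodes
  M <- bounds$molecules
  cap <- bounds$max_multiplicity
  if (cap > 2) stop("the encoding supports multiplicity caps 1 and 2")
  if (n > 8) stop("subset-based connectivity encoding supports at most 8 nodes")
  if (n < 2) stop("feasibility encoding needs at least 2 compartments")
  Mh <- M %/% 2

  # ordered pairs
  pair_u <- integer(0); pair_v <- integer(0)
  pidx <- matrix(0L, n, n)
  for (u in seq_len(n)) for (v in seq_len(n)) if (u != v) {
    pair_u <- c(pair_u, u); pair_v <- c(pair_v, v)
    pidx[u, v] <- length(pair_u)
  }
  P <- length(pair_u)

  cnf <- cnf_new()
  ev_off <- 0L;               nE <- P * 2L
  x_off <- nE;                nX <- n * M
  y_off <- x_off + nX;        nY <- P * 2L * M
  ax_off <- y_off + nY
  ay_off <- ax_off + nX
  pm_off <- ay_off + nY
  cnf_vars(cnf, pm_off + M * M)

  ev <- function(p, s) ev_off + (p - 1L) * 2L + s
  xv <- function(v, m) x_off + (v - 1L) * M + m
  yv <- function(p, s, m) y_off + ((p - 1L) * 2L + (s - 1L)) * M + m
  axv <- function(v, m) ax_off + (v - 1L) * M + m
  ayv <- function(p, s, m) ay_off + ((p - 1L) * 2L + (s - 1L)) * M + m
  pmv <- function(i, j) pm_off + (i - 1L) * M + j

  allp <- seq_len(P); allm <- seq_len(M)
  TT <- cnf_vars(cnf, 1L)      # constant TRUE
  cnf_clause(cnf, TT)

  ## ---- structure ----------------------------------------------------
  cnf_clauses_mat(cnf, cbind(-ev(allp, 2L), ev(allp, 1L)))
  if (cap == 1L) cnf_clauses_mat(cnf, cbind(-ev(allp, 2L)))
  g <- expand.grid(m = allm, s = 1:2, p = allp)
  cnf_clauses_mat(cnf, cbind(-yv(g$p, g$s, g$m), ev(g$p, g$s)))        # Y -> E
  cnf_clauses_mat(cnf, cbind(-yv(g$p, g$s, g$m), xv(pair_u[g$p], g$m))) # Y subset source
  cnf_clauses_mat(cnf, cbind(-yv(g$p, g$s, g$m), xv(pair_v[g$p], g$m))) # molecule must ride into a carrier node
  for (p in allp) for (s in 1:2)                                        # non-empty edges
    cnf_clause(cnf, c(-ev(p, s), yv(p, s, allm)))

  # parallel slots must carry distinct labels (identical parallel
  # vesicles would be one edge with doubled flux). Note: no
  # lexicographic ordering between the slot labels — that constraint
  # would not commute with the molecule-relabeling symmetry broken
  # below. The q chain tracks prefix equality of the two labels.
  if (cap == 2L) {
    for (p in allp) {
      q_prev <- TT
      for (m in allm) {
        qm <- cnf_vars(cnf, 1L)
        y1 <- yv(p, 1L, m); y2 <- yv(p, 2L, m)
        cnf_clause(cnf, c(-qm, q_prev))
        cnf_clause(cnf, c(-qm, y1, -y2))
        cnf_clause(cnf, c(-qm, -y1, y2))
        cnf_clause(cnf, c(qm, -q_prev, y1, y2))
        cnf_clause(cnf, c(qm, -q_prev, -y1, -y2))
        q_prev <- qm
      }
      cnf_clause(cnf, c(-ev(p, 2L), -q_prev))     # distinct when both present
    }
  }

  ## ---- pairing matrix (cross-class entries only) --------------------
  qs <- seq_len(Mh); rs <- seq.int(Mh + 1L, M)
  for (i in qs) for (j in qs) cnf_clause(cnf, -pmv(i, j))
  for (i in rs) for (j in rs) cnf_clause(cnf, -pmv(i, j))
  cross <- rbind(expand.grid(i = qs, j = rs), expand.grid(i = rs, j = qs))

  ## ---- activity: compartment side -----------------------------------
  gn <- expand.grid(m = allm, v = seq_len(n))
  if (regime$compartment_rule == "none") {
    cnf_clauses_mat(cnf, cbind(-axv(gn$v, gn$m), xv(gn$v, gn$m)))
    cnf_clauses_mat(cnf, cbind(axv(gn$v, gn$m), -xv(gn$v, gn$m)))
  } else {
    cnf_clauses_mat(cnf, cbind(-axv(gn$v, gn$m), xv(gn$v, gn$m)))
    if (n >= 2) for (a in seq_len(n - 1L)) for (b in seq.int(a + 1L, n)) {
      neq <- cnf_vars(cnf, M)
      cnf_clauses_mat(cnf, cbind(-neq, xv(a, allm), xv(b, allm)))
      cnf_clauses_mat(cnf, cbind(-neq, -xv(a, allm), -xv(b, allm)))
      for (i in allm) {
        cnf_clause(cnf, c(-axv(a, i), axv(b, i), neq))
        cnf_clause(cnf, c(axv(a, i), -axv(b, i), neq))
      }
    }
  }

  ## ---- activity: vesicle side ---------------------------------------
  slots <- expand.grid(s = 1:2, p = allp)   # all 2P slots
  gs <- expand.grid(m = allm, s = 1:2, p = allp)
  if (regime$vesicle_rule == "none") {
    cnf_clauses_mat(cnf, cbind(-ayv(gs$p, gs$s, gs$m), yv(gs$p, gs$s, gs$m)))
    cnf_clauses_mat(cnf, cbind(ayv(gs$p, gs$s, gs$m), -yv(gs$p, gs$s, gs$m)))
  } else if (regime$vesicle_rule == "boolean") {
    cnf_clauses_mat(cnf, cbind(-ayv(gs$p, gs$s, gs$m), yv(gs$p, gs$s, gs$m)))
    ns <- nrow(slots)
    for (a in seq_len(ns - 1L)) for (b in seq.int(a + 1L, ns)) {
      pa <- slots$p[a]; sa <- slots$s[a]
      pb <- slots$p[b]; sb <- slots$s[b]
      neq <- cnf_vars(cnf, M)
      cnf_clauses_mat(cnf, cbind(-neq, yv(pa, sa, allm), yv(pb, sb, allm)))
      cnf_clauses_mat(cnf, cbind(-neq, -yv(pa, sa, allm), -yv(pb, sb, allm)))
      for (i in allm) {
        cnf_clause(cnf, c(-ayv(pa, sa, i), ayv(pb, sb, i), neq))
        cnf_clause(cnf, c(ayv(pa, sa, i), -ayv(pb, sb, i), neq))
      }
    }
  } else {   # snare_inhibition
    opp <- function(i) if (i <= Mh) rs else qs
    for (r in seq_len(nrow(slots))) {
      p <- slots$p[r]; s <- slots$s[r]
      for (i in allm) {
        js <- opp(i)
        w <- cnf_vars(cnf, length(js))
        for (t in seq_along(js)) {
          j <- js[t]
          cnf_clause(cnf, c(-w[t], yv(p, s, j)))
          cnf_clause(cnf, c(-w[t], pmv(i, j), pmv(j, i)))
          cnf_clause(cnf, c(w[t], -yv(p, s, j), -pmv(i, j)))
          cnf_clause(cnf, c(w[t], -yv(p, s, j), -pmv(j, i)))
        }
        cnf_clause(cnf, c(-ayv(p, s, i), yv(p, s, i)))
        for (t in seq_along(js)) cnf_clause(cnf, c(-ayv(p, s, i), -w[t]))
        cnf_clause(cnf, c(ayv(p, s, i), -yv(p, s, i), w))
      }
    }
  }

  ## ---- fusion: C2 (edge valid against its target) -------------------
  for (p in allp) for (s in 1:2) {
    tv <- cnf_vars(cnf, nrow(cross))
    for (r in seq_len(nrow(cross))) {
      i <- cross$i[r]; j <- cross$j[r]
      cnf_clause(cnf, c(-tv[r], ayv(p, s, i)))
      cnf_clause(cnf, c(-tv[r], axv(pair_v[p], j)))
      cnf_clause(cnf, c(-tv[r], pmv(i, j)))
    }
    cnf_clause(cnf, c(-ev(p, s), tv))
  }

  ## ---- fusion: C3 (no competence with non-targets, incl. source) ----
  c3 <- NULL
  for (p in allp) for (z in seq_len(n)) {
    if (z == pair_v[p]) next
    for (s in 1:2)
      c3 <- rbind(c3, cbind(-ayv(p, s, cross$i), -axv(z, cross$j),
                            -pmv(cross$i, cross$j)))
  }
  cnf_clauses_mat(cnf, c3)

  ## ---- fusion: identical labels share a target ----------------------
  ns <- nrow(slots)
  if (ns >= 2) for (a in seq_len(ns - 1L)) for (b in seq.int(a + 1L, ns)) {
    pa <- slots$p[a]; sa <- slots$s[a]
    pb <- slots$p[b]; sb <- slots$s[b]
    if (pair_v[pa] == pair_v[pb]) next
    dd <- cnf_vars(cnf, M)
    cnf_clauses_mat(cnf, cbind(-dd, yv(pa, sa, allm), yv(pb, sb, allm)))
    cnf_clauses_mat(cnf, cbind(-dd, -yv(pa, sa, allm), -yv(pb, sb, allm)))
    cnf_clause(cnf, c(-ev(pa, sa), -ev(pb, sb), dd))
  }

  ## ---- steady state: step-indexed reachability ----------------------
  # arc(m, p) <-> some slot of p carries m
  arcv <- matrix(cnf_vars(cnf, M * P), M, P)
  for (m in allm) for (p in allp) {
    cnf_clause(cnf, c(-arcv[m, p], yv(p, 1L, m), yv(p, 2L, m)))
    cnf_clause(cnf, c(arcv[m, p], -yv(p, 1L, m)))
    cnf_clause(cnf, c(arcv[m, p], -yv(p, 2L, m)))
  }
  # reach_t(m, a, b), t = 1..n-1; reach_1 = arc
  reach <- vector("list", n - 1L)
  reach[[1L]] <- arcv            # indexed by [m, pidx[a,b]]
  if (n >= 3) for (t in 2:(n - 1L)) {
    rt <- matrix(cnf_vars(cnf, M * P), M, P)
    for (m in allm) for (p in allp) {
      a <- pair_u[p]; b <- pair_v[p]
      ws <- setdiff(seq_len(n), c(a, b))
      h <- cnf_vars(cnf, length(ws))
      for (wi in seq_along(ws)) {
        w <- ws[wi]
        cnf_clause(cnf, c(-h[wi], arcv[m, pidx[a, w]]))
        cnf_clause(cnf, c(-h[wi], reach[[t - 1L]][m, pidx[w, b]]))
        cnf_clause(cnf, c(h[wi], -arcv[m, pidx[a, w]],
                          -reach[[t - 1L]][m, pidx[w, b]]))
        cnf_clause(cnf, c(-h[wi], rt[m, p]))
      }
      cnf_clause(cnf, c(-reach[[t - 1L]][m, p], rt[m, p]))
      cnf_clause(cnf, c(-rt[m, p], reach[[t - 1L]][m, p], h))
    }
    reach[[t]] <- rt
  }
  # C1: molecule on an edge implies a return path target -> source
  rback <- reach[[n - 1L]]
  for (p in allp) for (s in 1:2) for (m in allm)
    cnf_clause(cnf, c(-yv(p, s, m), rback[m, pidx[pair_v[p], pair_u[p]]]))

  ## ---- structure constraints: topology / connectivity ---------------
  if (!is.null(fixed_topology)) {
    ft <- fixed_topology
    for (u in seq_len(n)) for (v in seq_len(n)) if (u != v) {
      p <- pidx[u, v]
      cnf_clause(cnf, if (ft[u, v] >= 1L) ev(p, 1L) else -ev(p, 1L))
      cnf_clause(cnf, if (ft[u, v] >= 2L) ev(p, 2L) else -ev(p, 2L))
    }
  } else {
    if (isTRUE(bounds$strongly_connected_only)) {
      for (mask in seq_len(2^n - 2L)) {
        inS <- bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0
        out_slots <- ev(pidx[cbind(
          rep(which(inS), each = sum(!inS)),
          rep(which(!inS), times = sum(inS)))], 1L)
        cnf_clause(cnf, out_slots)
      }
    }
    conn <- bounds$connectivity
    if (!is.null(conn)) {
      crossing_lits <- function(inS) {
        ps <- c(pidx[cbind(rep(which(inS), each = sum(!inS)),
                           rep(which(!inS), times = sum(inS)))],
                pidx[cbind(rep(which(!inS), each = sum(inS)),
                           rep(which(inS), times = sum(!inS)))])
        c(ev(ps, 1L), ev(ps, 2L))
      }
      masks <- 0:(2^(n - 1L) - 2L)   # node 1 in S, S proper
      geq <- switch(conn$type, geq = conn$k, exact = conn$k, below = 2L)
      for (mask in masks) {
        inS <- c(TRUE, bitwAnd(mask, 2^(seq_len(n - 1L) - 1L)) > 0)
        cnf_card_geq(cnf, crossing_lits(inS), geq)
      }
      if (conn$type %in% c("exact", "below")) {
        leq <- if (conn$type == "exact") conn$k else conn$k - 1L
        sels <- cnf_vars(cnf, length(masks))
        for (mi in seq_along(masks)) {
          inS <- c(TRUE, bitwAnd(masks[mi], 2^(seq_len(n - 1L) - 1L)) > 0)
          cnf_card_leq(cnf, crossing_lits(inS), leq, sel = sels[mi])
        }
        cnf_clause(cnf, sels)
      }
    }
    if (!is.null(bounds$edge_budget))
      cnf_card_leq(cnf, as.integer(sapply(allp, function(p) c(ev(p, 1L), ev(p, 2L)))),
                   bounds$edge_budget)
  }

  ## ---- symmetry breaking (lex-leader under adjacent transpositions) --
  # The model is equivariant under permutations of molecule types
  # within the Q block / within the R block, and (when structure is
  # free) under permutations of the node labels. For each adjacent
  # transposition sigma (an involution) we post V <=lex sigma(V) over
  # the core variables in allocation order: every symmetry orbit keeps
  # its lex-minimal member, so satisfiability is preserved while UNSAT
  # proofs shrink by large factors. Iterating variable ids ascending
  # and comparing id against image (keeping only id < image) yields the
  # standard involution short-cut of the full lex-leader constraint.
  n_core <- pm_off + M * M
  lex_leader <- function(perm) {
    ids <- which(perm != seq_len(n_core) & seq_len(n_core) < perm)
    if (!length(ids)) return(invisible(NULL))
    e_prev <- TT
    for (t in seq_along(ids)) {
      v0 <- ids[t]; w0 <- perm[ids[t]]
      cnf_clause(cnf, c(-e_prev, -v0, w0))
      if (t < length(ids)) {
        et <- cnf_vars(cnf, 1L)
        cnf_clause(cnf, c(-e_prev, -v0, -w0, et))
        cnf_clause(cnf, c(-e_prev, v0, w0, et))
        e_prev <- et
      }
    }
  }
  mol_perm <- function(i) {       # swap molecule types i and i+1
    sw <- function(m) ifelse(m == i, i + 1L, ifelse(m == i + 1L, i, m))
    perm <- seq_len(n_core)
    for (v in seq_len(n)) {
      perm[xv(v, i)] <- xv(v, i + 1L); perm[xv(v, i + 1L)] <- xv(v, i)
      perm[axv(v, i)] <- axv(v, i + 1L); perm[axv(v, i + 1L)] <- axv(v, i)
    }
    for (p in allp) for (s in 1:2) {
      perm[yv(p, s, i)] <- yv(p, s, i + 1L); perm[yv(p, s, i + 1L)] <- yv(p, s, i)
      perm[ayv(p, s, i)] <- ayv(p, s, i + 1L); perm[ayv(p, s, i + 1L)] <- ayv(p, s, i)
    }
    for (a in allm) for (b in allm)
      perm[pmv(a, b)] <- pmv(sw(a), sw(b))
    perm
  }
  for (i in c(seq_len(Mh - 1L), if (Mh >= 2L) seq.int(Mh + 1L, M - 1L)))
    lex_leader(mol_perm(i))
  if (is.null(fixed_topology) && n >= 2) {
    node_perm <- function(u) {    # swap node labels u and u+1
      w <- u + 1L
      sw <- function(z) ifelse(z == u, w, ifelse(z == w, u, z))
      perm <- seq_len(n_core)
      for (m in allm) {
        perm[xv(u, m)] <- xv(w, m); perm[xv(w, m)] <- xv(u, m)
        perm[axv(u, m)] <- axv(w, m); perm[axv(w, m)] <- axv(u, m)
      }
      for (p in allp) {
        sp <- pidx[sw(pair_u[p]), sw(pair_v[p])]
        if (sp == p) next
        for (s in 1:2) {
          perm[ev(p, s)] <- ev(sp, s)
          for (m in allm) {
            perm[yv(p, s, m)] <- yv(sp, s, m)
            perm[ayv(p, s, m)] <- ayv(sp, s, m)
          }
        }
      }
      perm
    }
    for (u in seq_len(n - 1L)) lex_leader(node_perm(u))
  }

  varmap <- list(n = n, M = M, P = P, pair_u = pair_u, pair_v = pair_v,
                 pidx = pidx, ev = ev, xv = xv, yv = yv, axv = axv,
                 ayv = ayv, pmv = pmv)
  structure(list(cnf = cnf, varmap = varmap, bounds = bounds,
                 regime = regime, fixed_topology = fixed_topology),
            class = "vt_encoding")
}

#' Decode a SAT model into a network instance
#'
#' Reads the structure, composition, pairing and activity variables of
#' a satisfying assignment back into a [network_instance()]. Boolean
#' regulation functions are materialized as explicit maps over the
#' compositions realized in the model; unrealized compositions default
#' to all-inactive.
#'
#' @param verdict a SAT [solve_cnf()] verdict.
#' @param encoding the matching [encode_feasibility()] result.
#' @return a `vt_instance`.
#' @export
decode_instance <- function(verdict, encoding) {
  if (!identical(verdict$status, "SAT"))
    stop("cannot decode an UNSAT verdict")
  vm <- encoding$varmap
  model <- verdict$model
  if (length(model) < encoding$cnf$nvars)
    stop("model does not match the encoding")
  n <- vm$n; M <- vm$M
  uni <- molecule_universe(M)
  ids <- paste0("n", seq_len(n))
  comps <- list()
  for (v in seq_len(n))
    comps[[ids[v]]] <- as.integer(model[vm$xv(v, seq_len(M))])
  edges <- list()
  eact <- list()
  for (p in seq_len(vm$P)) for (s in 1:2) {
    if (!model[vm$ev(p, s)]) next
    comp <- as.integer(model[vm$yv(p, s, seq_len(M))])
    edges[[length(edges) + 1L]] <-
      vesicle_edge(ids[vm$pair_u[p]], ids[vm$pair_v[p]], comp)
    eact[[length(eact) + 1L]] <- as.integer(model[vm$ayv(p, s, seq_len(M))])
  }
  net <- transport_network(uni, comps, edges, check = FALSE)
  pm <- matrix(0L, M, M)
  for (i in seq_len(M)) pm[i, ] <- as.integer(model[vm$pmv(i, seq_len(M))])
  pairing <- pairing_matrix(pm, uni)
  regime <- encoding$regime
  reg <- NULL
  if (regime$compartment_rule == "boolean" || regime$vesicle_rule == "boolean") {
    cmap <- NULL; vmap <- NULL
    if (regime$compartment_rule == "boolean") {
      cmap <- character()
      for (v in seq_len(n)) {
        key <- comp_to_string(comps[[ids[v]]], space = FALSE)
        cmap[key] <- comp_to_string(
          as.integer(model[vm$axv(v, seq_len(M))]), space = FALSE)
      }
    }
    if (regime$vesicle_rule == "boolean") {
      vmap <- character()
      for (i in seq_along(edges)) {
        key <- comp_to_string(edges[[i]]$composition, space = FALSE)
        vmap[key] <- comp_to_string(eact[[i]], space = FALSE)
      }
    }
    reg <- regulation_function(compartment = cmap, vesicle = vmap)
  }
  network_instance(net, pairing, regime, reg)
}
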