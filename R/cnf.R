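# CNF construction and solving: a growable clause buffer, sequential
# counter cardinality encodings, DIMACS export, and the interface to
# the bundled CDCL solver.

#' CNF problem builder
#'
#' A mutable clause buffer. Variables are contiguous from 1 and must be
#' allocated through [cnf_vars()]; clauses are integer vectors of
#' non-zero DIMACS literals. Empty clauses are rejected at build time.
#'
#' @return `vt_cnf` environment.
#' @export
cnf_new <- function() {
  e <- new.env(parent = emptyenv())
  e$nvars <- 0L
  e$lits <- integer(1024L); e$nlit <- 0L
  e$lens <- integer(256L); e$nclause <- 0L
  class(e) <- "vt_cnf"
  e
}

#' @rdname cnf_new
#' @param cnf a `vt_cnf`.
#' @param k number of fresh variables.
#' @return integer vector of the new variable ids.
#' @export
cnf_vars <- function(cnf, k) {
  ids <- cnf$nvars + seq_len(k)
  cnf$nvars <- cnf$nvars + as.integer(k)
  ids
}

#' @rdname cnf_new
#' @param lits integer literal vector (one clause).
#' @export
cnf_clause <- function(cnf, lits) {
  n <- length(lits)
  if (n == 0L) stop("refusing to add an empty clause")
  need <- cnf$nlit + n
  if (need > length(cnf$lits))
    cnf$lits <- c(cnf$lits, integer(max(length(cnf$lits), n)))
  cnf$lits[(cnf$nlit + 1L):need] <- as.integer(lits)
  cnf$nlit <- as.integer(need)
  if (cnf$nclause + 1L > length(cnf$lens))
    cnf$lens <- c(cnf$lens, integer(length(cnf$lens)))
  cnf$nclause <- cnf$nclause + 1L
  cnf$lens[cnf$nclause] <- as.integer(n)
  invisible(cnf)
}

# add many fixed-width clauses at once (rows of an integer matrix)
cnf_clauses_mat <- function(cnf, m) {
  if (is.null(m) || nrow(m) == 0) return(invisible(cnf))
  w <- ncol(m)
  flat <- as.integer(t(m))
  need <- cnf$nlit + length(flat)
  if (need > length(cnf$lits))
    cnf$lits <- c(cnf$lits, integer(max(length(cnf$lits), length(flat))))
  cnf$lits[(cnf$nlit + 1L):need] <- flat
  cnf$nlit <- as.integer(need)
  nc <- nrow(m)
  if (cnf$nclause + nc > length(cnf$lens))
    cnf$lens <- c(cnf$lens, integer(max(length(cnf$lens), nc)))
  cnf$lens[(cnf$nclause + 1L):(cnf$nclause + nc)] <- w
  cnf$nclause <- cnf$nclause + as.integer(nc)
  invisible(cnf)
}

#' @rdname cnf_new
#' @export
cnf_size <- function(cnf) {
  c(variables = cnf$nvars, clauses = cnf$nclause)
}

# sequential-counter cardinality: at least k of lits are true
cnf_card_geq <- function(cnf, lits, k) {
  L <- length(lits)
  k <- as.integer(k)
  if (k <= 0L) return(invisible(cnf))
  if (k > L) {  # unsatisfiable: fresh contradiction
    v <- cnf_vars(cnf, 1L)
    cnf_clause(cnf, v); cnf_clause(cnf, -v)
    return(invisible(cnf))
  }
  if (k == 1L) return(cnf_clause(cnf, lits))
  # registers r[i, j]: at least j true among the first i literals
  r <- matrix(cnf_vars(cnf, L * k), L, k)
  for (i in seq_len(L)) for (j in seq_len(k)) {
    if (i == 1L) {
      if (j == 1L) cnf_clause(cnf, c(-r[1, 1], lits[1]))
      else cnf_clause(cnf, -r[1, j])
    } else {
      cnf_clause(cnf, c(-r[i, j], r[i - 1, j], lits[i]))
      if (j > 1L) cnf_clause(cnf, c(-r[i, j], r[i - 1, j], r[i - 1, j - 1]))
    }
  }
  cnf_clause(cnf, r[L, k])
  invisible(cnf)
}

# sequential-counter cardinality: at most k of lits are true; when
# `sel` is given the constraint is conditional on sel being true
cnf_card_leq <- function(cnf, lits, k, sel = NULL) {
  L <- length(lits)
  k <- as.integer(k)
  guard <- if (is.null(sel)) integer(0) else -as.integer(sel)
  if (k >= L) return(invisible(cnf))
  if (k == 0L) {
    for (l in lits) cnf_clause(cnf, c(guard, -l))
    return(invisible(cnf))
  }
  r <- matrix(cnf_vars(cnf, (L - 1L) * k), L - 1L, k)
  for (i in seq_len(L - 1L)) {
    cnf_clause(cnf, c(-lits[i], r[i, 1]))
    if (i > 1L) {
      for (j in seq_len(k)) cnf_clause(cnf, c(-r[i - 1, j], r[i, j]))
      if (k > 1L) for (j in seq.int(2L, k))
        cnf_clause(cnf, c(-lits[i], -r[i - 1, j - 1L], r[i, j]))
    }
    if (i > 1L) cnf_clause(cnf, c(guard, -lits[i], -r[i - 1, k]))
  }
  cnf_clause(cnf, c(guard, -lits[L], -r[L - 1L, k]))
  invisible(cnf)
}

#' Write a CNF problem in DIMACS format
#'
#' @param cnf a `vt_cnf`.
#' @param path output file.
#' @param comments optional character vector of comment lines.
#' @export
write_dimacs <- function(cnf, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste("c", cm), con)
  writeLines(sprintf("p cnf %d %d", cnf$nvars, cnf$nclause), con)
  ends <- cumsum(cnf$lens[seq_len(cnf$nclause)])
  starts <- c(1L, head(ends, -1L) + 1L)
  lines <- vapply(seq_len(cnf$nclause), function(i)
    paste(c(cnf$lits[starts[i]:ends[i]], 0L), collapse = " "), "")
  writeLines(lines, con)
  invisible(path)
}

#' Solve a CNF problem
#'
#' Runs the bundled CDCL solver. The SAT/UNSAT status is independent of
#' the seed (which only perturbs branching tie-breaks); the model, when
#' SAT, is deterministic given seed and solver version.
#'
#' @param cnf a `vt_cnf`.
#' @param seed non-negative integer.
#' @param assumptions optional integer literal vector appended as unit
#'   clauses (used to fix structure variables to a topology).
#' @param max_conflicts optional conflict budget; when exhausted the
#'   status is `"UNKNOWN"` (used by workflows that fall back to
#'   per-topology decomposition).
#' @return `vt_verdict`: list(status = "SAT"/"UNSAT"/"UNKNOWN", model
#'   (logical vector indexed by variable, NULL unless SAT), conflicts,
#'   decisions, seed).
#' @export
solve_cnf <- function(cnf, seed = 0, assumptions = NULL,
                      max_conflicts = -1) {
  nl <- cnf$nlit; nc <- cnf$nclause
  lits <- cnf$lits[seq_len(nl)]
  lens <- cnf$lens[seq_len(nc)]
  if (!is.null(assumptions) && length(assumptions)) {
    lits <- c(lits, as.integer(assumptions))
    lens <- c(lens, rep(1L, length(assumptions)))
  }
  res <- .sat_solve_cpp(cnf$nvars, lits, lens, as.integer(seed),
                        as.numeric(max_conflicts))
  model <- if (identical(res$status, "SAT")) res$model == 1L else NULL
  structure(list(status = res$status, model = model,
                 conflicts = res$conflicts, decisions = res$decisions,
                 seed = seed),
            class = "vt_verdict")
}

#' @export
print.vt_verdict <- function(x, ...) {
  cat("SAT verdict:", x$status,
      sprintf("(%.0f conflicts, %.0f decisions, seed %d)\n",
              x$conflicts, x$decisions, x$seed))
  invisible(x)
}
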