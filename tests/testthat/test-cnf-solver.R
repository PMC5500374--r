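test_that("trivial formulas", {
  cnf <- cnf_new(); x <- cnf_vars(cnf, 1)
  cnf_clause(cnf, x)
  expect_equal(solve_cnf(cnf)$status, "SAT")
  cnf_clause(cnf, -x)
  expect_equal(solve_cnf(cnf)$status, "UNSAT")
  expect_error(cnf_clause(cnf, integer(0)), "empty clause")
})

test_that("solver agrees with brute force on random formulas", {
  set.seed(101)
  for (rep in 1:120) {
    nv <- sample(3:11, 1)
    nc <- sample(2:(4 * nv), 1)
    clauses <- lapply(seq_len(nc), function(i) {
      vars <- sample(nv, sample(1:3, 1))
      vars * sample(c(-1, 1), length(vars), replace = TRUE)
    })
    cnf <- cnf_new(); cnf_vars(cnf, nv)
    for (cl in clauses) cnf_clause(cnf, cl)
    v <- solve_cnf(cnf, seed = rep %% 7)
    expect_equal(v$status == "SAT", brute_sat(nv, clauses))
    if (v$status == "SAT") {
      model <- v$model
      expect_true(all(vapply(clauses, function(cl)
        any((cl > 0 & model[abs(cl)]) | (cl < 0 & !model[abs(cl)])), TRUE)))
    }
  }
})

test_that("pigeonhole is UNSAT and budget reports UNKNOWN", {
  ph <- cnf_new(); v <- matrix(cnf_vars(ph, 20), 5, 4)
  for (p in 1:5) cnf_clause(ph, v[p, ])
  for (h in 1:4) for (p1 in 1:4) for (p2 in (p1 + 1):5)
    cnf_clause(ph, c(-v[p1, h], -v[p2, h]))
  expect_equal(solve_cnf(ph)$status, "UNSAT")
  expect_equal(solve_cnf(ph, max_conflicts = 1)$status, "UNKNOWN")
})

test_that("cardinality encodings agree with popcount semantics", {
  set.seed(202)
  for (rep in 1:80) {
    L <- sample(2:8, 1); k <- sample(0:(L + 1), 1)
    cnf <- cnf_new(); lits <- cnf_vars(cnf, L)
    truth <- sample(c(TRUE, FALSE), L, replace = TRUE)
    for (i in seq_len(L)) cnf_clause(cnf, if (truth[i]) lits[i] else -lits[i])
    if (rep %% 2 == 0) {
      snaresat:::cnf_card_geq(cnf, lits, k)
      expect_equal(solve_cnf(cnf)$status == "SAT", sum(truth) >= k)
    } else {
      snaresat:::cnf_card_leq(cnf, lits, k)
      expect_equal(solve_cnf(cnf)$status == "SAT", sum(truth) <= k)
    }
  }
  # conditional at-most via selector literal
  cnf <- cnf_new(); lits <- cnf_vars(cnf, 4); sel <- cnf_vars(cnf, 1)
  for (l in lits) cnf_clause(cnf, l)       # all four true
  snaresat:::cnf_card_leq(cnf, lits, 2, sel = sel)
  cnf_clause(cnf, sel)
  expect_equal(solve_cnf(cnf)$status, "UNSAT")
  cnf2 <- cnf_new(); lits <- cnf_vars(cnf2, 4); sel <- cnf_vars(cnf2, 1)
  for (l in lits) cnf_clause(cnf2, l)
  snaresat:::cnf_card_leq(cnf2, lits, 2, sel = sel)
  cnf_clause(cnf2, -sel)                   # constraint disabled
  expect_equal(solve_cnf(cnf2)$status, "SAT")
})

test_that("status is invariant under the solver seed", {
  b <- search_bounds(2, 4, strongly_connected_only = TRUE)
  enc_sat <- encode_feasibility(b, regime_row(1), nodes = 2)
  enc_unsat <- encode_feasibility(b, regime_row(6), nodes = 2)
  for (seed in c(0, 1, 17)) {
    expect_equal(solve_cnf(enc_sat$cnf, seed = seed)$status, "SAT")
    expect_equal(solve_cnf(enc_unsat$cnf, seed = seed)$status, "UNSAT")
  }
})

test_that("DIMACS export is well-formed", {
  cnf <- cnf_new(); x <- cnf_vars(cnf, 3)
  cnf_clause(cnf, c(x[1], -x[2]))
  cnf_clause(cnf, c(-x[1], x[2], x[3]))
  path <- tempfile(fileext = ".cnf")
  write_dimacs(cnf, path, comments = "test formula")
  lines <- readLines(path)
  expect_equal(lines[1], "c test formula")
  expect_equal(lines[2], "p cnf 3 2")
  expect_equal(lines[3], "1 -2 0")
  expect_equal(lines[4], "-1 2 3 0")
})
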