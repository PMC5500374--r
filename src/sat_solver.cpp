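// Conflict-driven clause-learning (CDCL) SAT solver, MiniSat-style:
// two-literal watching, first-UIP learning, VSIDS branching with phase
// saving, Luby restarts, activity-based learnt-clause reduction.
// Bundled so the package has no external solver dependency; the public
// R entry point is sat_solve_cpp() (DIMACS-style integer literals).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdlib>
#include <algorithm>

namespace {

typedef int Lit;   // 2*var + sign (sign 1 = negated), var is 0-based
typedef int Var;

inline Lit mkLit(Var v, bool neg) { return 2 * v + (neg ? 1 : 0); }
inline Lit negLit(Lit p) { return p ^ 1; }
inline Var litVar(Lit p) { return p >> 1; }
inline bool litSign(Lit p) { return p & 1; }

enum { L_UNDEF = 0, L_TRUE = 1, L_FALSE = 2 };

struct Clause {
    std::vector<Lit> lits;
    double act;
    bool learnt;
    Clause() : act(0.0), learnt(false) {}
};

class Solver {
public:
    int nvars;
    std::vector<Clause> clauses;           // index = clause ref
    std::vector<std::vector<int> > watches; // per literal: clause refs
    std::vector<unsigned char> assigns;    // per var: L_*
    std::vector<unsigned char> phase;      // saved phase (1 = last was true)
    std::vector<int> level;                // per var
    std::vector<int> reason;               // per var: clause ref or -1
    std::vector<Lit> trail;
    std::vector<int> trail_lim;
    size_t qhead;

    // VSIDS
    std::vector<double> activity;
    double var_inc, var_decay;
    std::vector<int> heap;                 // binary max-heap of vars
    std::vector<int> heap_pos;             // var -> index in heap or -1

    double cla_inc;
    long long conflicts, propagations, decisions;
    int n_learnt;
    bool ok;
    unsigned long long rng_state;

    Solver(int nv, unsigned int seed)
        : nvars(nv), watches(2 * nv), assigns(nv, L_UNDEF), phase(nv, 0),
          level(nv, 0), reason(nv, -1), qhead(0), activity(nv, 0.0),
          var_inc(1.0), var_decay(0.95), heap_pos(nv, -1), cla_inc(1.0),
          conflicts(0), propagations(0), decisions(0), n_learnt(0), ok(true),
          rng_state(seed * 2654435761ULL + 1442695040888963407ULL) {
        // tiny seed-dependent jitter keeps branching ties deterministic per
        // seed without affecting the SAT/UNSAT status
        for (Var v = 0; v < nvars; v++) {
            activity[v] = 1e-9 * (double)(nextRnd() % 1024);
            heapInsert(v);
        }
    }

    unsigned long long nextRnd() {
        rng_state = rng_state * 6364136223846793005ULL + 1442695040888963407ULL;
        return rng_state >> 17;
    }

    // ---- heap ----------------------------------------------------------
    bool heapLess(int a, int b) const { return activity[a] > activity[b]; }
    void heapSiftUp(int i) {
        int v = heap[i];
        while (i > 0) {
            int p = (i - 1) >> 1;
            if (heapLess(v, heap[p])) { heap[i] = heap[p]; heap_pos[heap[i]] = i; i = p; }
            else break;
        }
        heap[i] = v; heap_pos[v] = i;
    }
    void heapSiftDown(int i) {
        int v = heap[i];
        int n = (int)heap.size();
        for (;;) {
            int c = 2 * i + 1;
            if (c >= n) break;
            if (c + 1 < n && heapLess(heap[c + 1], heap[c])) c++;
            if (heapLess(heap[c], v)) { heap[i] = heap[c]; heap_pos[heap[i]] = i; i = c; }
            else break;
        }
        heap[i] = v; heap_pos[v] = i;
    }
    void heapInsert(Var v) {
        if (heap_pos[v] >= 0) return;
        heap.push_back(v);
        heap_pos[v] = (int)heap.size() - 1;
        heapSiftUp((int)heap.size() - 1);
    }
    Var heapPop() {
        int v = heap[0];
        heap[0] = heap.back(); heap_pos[heap[0]] = 0;
        heap.pop_back(); heap_pos[v] = -1;
        if (!heap.empty()) heapSiftDown(0);
        return v;
    }
    void heapUpdate(Var v) { if (heap_pos[v] >= 0) heapSiftUp(heap_pos[v]); }

    // ---- state ---------------------------------------------------------
    int valueLit(Lit p) const {
        unsigned char a = assigns[litVar(p)];
        if (a == L_UNDEF) return L_UNDEF;
        bool t = (a == L_TRUE);
        if (litSign(p)) t = !t;
        return t ? L_TRUE : L_FALSE;
    }
    int decisionLevel() const { return (int)trail_lim.size(); }

    void uncheckedEnqueue(Lit p, int from) {
        Var v = litVar(p);
        assigns[v] = litSign(p) ? L_FALSE : L_TRUE;
        level[v] = decisionLevel();
        reason[v] = from;
        trail.push_back(p);
    }

    void cancelUntil(int lvl) {
        if (decisionLevel() <= lvl) return;
        for (int i = (int)trail.size() - 1; i >= trail_lim[lvl]; i--) {
            Var v = litVar(trail[i]);
            phase[v] = (assigns[v] == L_TRUE) ? 1 : 0;
            assigns[v] = L_UNDEF;
            reason[v] = -1;
            heapInsert(v);
        }
        trail.resize(trail_lim[lvl]);
        trail_lim.resize(lvl);
        qhead = trail.size();
    }

    // ---- clause management --------------------------------------------
    void attach(int cref) {
        Clause &c = clauses[cref];
        watches[negLit(c.lits[0])].push_back(cref);
        watches[negLit(c.lits[1])].push_back(cref);
    }
    void detach(int cref) {
        Clause &c = clauses[cref];
        for (int k = 0; k < 2; k++) {
            std::vector<int> &w = watches[negLit(c.lits[k])];
            for (size_t i = 0; i < w.size(); i++)
                if (w[i] == cref) { w[i] = w.back(); w.pop_back(); break; }
        }
    }

    // add original clause; returns false on immediate conflict
    bool addClause(std::vector<Lit> &ps) {
        if (!ok) return false;
        std::sort(ps.begin(), ps.end());
        std::vector<Lit> out;
        Lit prev = -1;
        for (size_t i = 0; i < ps.size(); i++) {
            Lit p = ps[i];
            if (valueLit(p) == L_TRUE) return true;          // satisfied at level 0
            if (p == negLit(prev)) return true;              // tautology
            if (p != prev && valueLit(p) != L_FALSE) out.push_back(p);
            prev = p;
        }
        if (out.empty()) { ok = false; return false; }
        if (out.size() == 1) {
            uncheckedEnqueue(out[0], -1);
            return ok = (propagate() == -1);
        }
        clauses.push_back(Clause());
        clauses.back().lits = out;
        attach((int)clauses.size() - 1);
        return true;
    }

    void claBump(int cref) {
        Clause &c = clauses[cref];
        if (!c.learnt) return;
        c.act += cla_inc;
        if (c.act > 1e20) {
            for (size_t i = 0; i < clauses.size(); i++)
                if (clauses[i].learnt) clauses[i].act *= 1e-20;
            cla_inc *= 1e-20;
        }
    }
    void varBump(Var v) {
        activity[v] += var_inc;
        if (activity[v] > 1e100) {
            for (Var x = 0; x < nvars; x++) activity[x] *= 1e-100;
            var_inc *= 1e-100;
        }
        heapUpdate(v);
    }

    // ---- propagation ---------------------------------------------------
    int propagate() { // returns conflicting clause ref or -1
        while (qhead < trail.size()) {
            Lit p = trail[qhead++];
            propagations++;
            std::vector<int> &ws = watches[p];
            size_t i = 0, j = 0;
            while (i < ws.size()) {
                int cref = ws[i];
                Clause &c = clauses[cref];
                // make sure the false literal is lits[1]
                Lit fl = negLit(p);
                if (c.lits[0] == fl) std::swap(c.lits[0], c.lits[1]);
                if (valueLit(c.lits[0]) == L_TRUE) { ws[j++] = ws[i++]; continue; }
                bool moved = false;
                for (size_t k = 2; k < c.lits.size(); k++) {
                    if (valueLit(c.lits[k]) != L_FALSE) {
                        std::swap(c.lits[1], c.lits[k]);
                        watches[negLit(c.lits[1])].push_back(cref);
                        moved = true;
                        break;
                    }
                }
                if (moved) { i++; continue; }
                // unit or conflict
                ws[j++] = ws[i++];
                if (valueLit(c.lits[0]) == L_FALSE) {
                    // conflict: copy remaining watches and bail
                    while (i < ws.size()) ws[j++] = ws[i++];
                    ws.resize(j);
                    qhead = trail.size();
                    return cref;
                }
                uncheckedEnqueue(c.lits[0], cref);
            }
            ws.resize(j);
        }
        return -1;
    }

    // ---- conflict analysis (first UIP) --------------------------------
    std::vector<unsigned char> seen;
    void analyze(int confl, std::vector<Lit> &out_learnt, int &out_btlevel) {
        if (seen.empty()) seen.assign(nvars, 0);
        std::vector<Var> toclear;
        int pathC = 0;
        Lit p = -1;
        out_learnt.clear();
        out_learnt.push_back(-1); // placeholder for asserting literal
        int index = (int)trail.size() - 1;

        do {
            Clause &c = clauses[confl];
            claBump(confl);
            for (size_t k = (p == -1 ? 0 : 1); k < c.lits.size(); k++) {
                Lit q = c.lits[k];
                Var v = litVar(q);
                if (!seen[v] && level[v] > 0) {
                    seen[v] = 1;
                    toclear.push_back(v);
                    varBump(v);
                    if (level[v] >= decisionLevel()) pathC++;
                    else out_learnt.push_back(q);
                }
            }
            while (!seen[litVar(trail[index])]) index--;
            p = trail[index--];
            seen[litVar(p)] = 0;
            confl = reason[litVar(p)];
            pathC--;
        } while (pathC > 0);
        out_learnt[0] = negLit(p);

        // simple self-subsumption minimization
        size_t i2, j2;
        std::vector<Lit> &lr = out_learnt;
        for (i2 = j2 = 1; i2 < lr.size(); i2++) {
            Var v = litVar(lr[i2]);
            int r = reason[v];
            if (r == -1) { lr[j2++] = lr[i2]; continue; }
            bool redundant = true;
            Clause &rc = clauses[r];
            for (size_t k = 1; k < rc.lits.size(); k++) {
                Var w = litVar(rc.lits[k]);
                if (!seen[w] && level[w] > 0) { redundant = false; break; }
            }
            if (!redundant) lr[j2++] = lr[i2];
        }
        lr.resize(j2);

        if (lr.size() == 1) out_btlevel = 0;
        else {
            int maxi = 1;
            for (size_t k = 2; k < lr.size(); k++)
                if (level[litVar(lr[k])] > level[litVar(lr[maxi])]) maxi = (int)k;
            std::swap(lr[1], lr[maxi]);
            out_btlevel = level[litVar(lr[1])];
        }
        for (size_t k = 0; k < toclear.size(); k++) seen[toclear[k]] = 0;
    }

    // ---- learnt DB reduction ------------------------------------------
    std::vector<int> learnt_refs;
    void reduceDB() {
        std::vector<int> cand;
        for (size_t i = 0; i < learnt_refs.size(); i++) {
            int cref = learnt_refs[i];
            if (clauses[cref].lits.size() > 2 && !locked(cref)) cand.push_back(cref);
        }
        if (cand.size() < 2) return;
        std::sort(cand.begin(), cand.end(),
                  [this](int a, int b) { return clauses[a].act < clauses[b].act; });
        size_t nrm = cand.size() / 2;
        std::vector<unsigned char> dead(clauses.size(), 0);
        for (size_t i = 0; i < nrm; i++) { detach(cand[i]); dead[cand[i]] = 1; }
        std::vector<int> keep;
        for (size_t i = 0; i < learnt_refs.size(); i++)
            if (!dead[learnt_refs[i]]) keep.push_back(learnt_refs[i]);
        learnt_refs.swap(keep);
        n_learnt = (int)learnt_refs.size();
        // note: dead clause bodies stay in the arena (indices stable);
        // acceptable for the problem sizes this package generates
    }
    bool locked(int cref) const {
        const Clause &c = clauses[cref];
        Var v = litVar(c.lits[0]);
        return assigns[v] != L_UNDEF && reason[v] == cref &&
               valueLit(c.lits[0]) == L_TRUE;
    }

    // ---- Luby sequence -------------------------------------------------
    static double luby(double y, int x) {
        int size, seq;
        for (size = 1, seq = 0; size < x + 1; seq++, size = 2 * size + 1) {}
        while (size - 1 != x) { size = (size - 1) >> 1; seq--; x = x % size; }
        return std::pow(y, seq);
    }

    // ---- main search ---------------------------------------------------
    // returns 1 = SAT, 0 = UNSAT, 2 = conflict budget exhausted
    int solve(long long max_conflicts) {
        if (!ok) return 0;
        int curr_restarts = 0;
        double max_learnts = std::max((size_t)1000, clauses.size() / 3);
        for (;;) {
            long long budget = (long long)(luby(2.0, curr_restarts) * 100.0);
            if (max_conflicts >= 0 && conflicts + budget > max_conflicts)
                budget = max_conflicts - conflicts;
            if (max_conflicts >= 0 && budget <= 0) return 2;
            int st = search(budget, max_learnts);
            if (st != -1) return st;
            if (max_conflicts >= 0 && conflicts >= max_conflicts) return 2;
            curr_restarts++;
            if (curr_restarts % 10 == 0) max_learnts *= 1.1;
            Rcpp::checkUserInterrupt();
        }
    }

    int search(long long nof_conflicts, double &max_learnts) {
        long long conflictC = 0;
        std::vector<Lit> learnt;
        for (;;) {
            int confl = propagate();
            if (confl != -1) {
                conflicts++; conflictC++;
                if (decisionLevel() == 0) return 0;  // UNSAT
                int btlevel;
                analyze(confl, learnt, btlevel);
                cancelUntil(btlevel);
                if (learnt.size() == 1) {
                    uncheckedEnqueue(learnt[0], -1);
                } else {
                    clauses.push_back(Clause());
                    int cref = (int)clauses.size() - 1;
                    clauses[cref].lits = learnt;
                    clauses[cref].learnt = true;
                    clauses[cref].act = cla_inc;
                    attach(cref);
                    learnt_refs.push_back(cref);
                    n_learnt++;
                    uncheckedEnqueue(learnt[0], cref);
                }
                var_inc /= var_decay;
                cla_inc /= 0.999;
            } else {
                if (conflictC >= nof_conflicts) { cancelUntil(0); return -1; }
                if (n_learnt >= (int)max_learnts) reduceDB();
                // decide
                Var next = -1;
                while (!heap.empty()) {
                    Var v = heapPop();
                    if (assigns[v] == L_UNDEF) { next = v; break; }
                }
                if (next == -1) return 1;  // SAT
                decisions++;
                trail_lim.push_back((int)trail.size());
                uncheckedEnqueue(mkLit(next, phase[next] == 0), -1);
            }
        }
    }
};

} // namespace

//' @noRd
// [[Rcpp::export(name = ".sat_solve_cpp")]]
Rcpp::List sat_solve_cpp(int nvars, Rcpp::IntegerVector lits,
                         Rcpp::IntegerVector lens, int seed,
                         double max_conflicts) {
    Solver S(nvars, (unsigned int)seed);
    std::vector<Lit> cl;
    int pos = 0;
    for (int i = 0; i < lens.size(); i++) {
        cl.clear();
        for (int k = 0; k < lens[i]; k++) {
            int d = lits[pos++];
            if (d == 0 || std::abs(d) > nvars)
                Rcpp::stop("literal out of range in clause %d", i + 1);
            cl.push_back(mkLit(std::abs(d) - 1, d < 0));
        }
        if (cl.empty()) Rcpp::stop("empty clause at position %d", i + 1);
        if (!S.addClause(cl)) {
            return Rcpp::List::create(
                Rcpp::Named("status") = "UNSAT",
                Rcpp::Named("model") = R_NilValue,
                Rcpp::Named("conflicts") = (double)S.conflicts,
                Rcpp::Named("decisions") = (double)S.decisions);
        }
    }
    int st = S.solve(max_conflicts < 0 ? -1 : (long long)max_conflicts);
    if (st == 2) {
        return Rcpp::List::create(
            Rcpp::Named("status") = "UNKNOWN",
            Rcpp::Named("model") = R_NilValue,
            Rcpp::Named("conflicts") = (double)S.conflicts,
            Rcpp::Named("decisions") = (double)S.decisions);
    }
    if (st == 1) {
        Rcpp::IntegerVector model(nvars);
        for (int v = 0; v < nvars; v++)
            model[v] = (S.assigns[v] == L_TRUE) ? 1 : 0;
        return Rcpp::List::create(
            Rcpp::Named("status") = "SAT",
            Rcpp::Named("model") = model,
            Rcpp::Named("conflicts") = (double)S.conflicts,
            Rcpp::Named("decisions") = (double)S.decisions);
    }
    return Rcpp::List::create(
        Rcpp::Named("status") = "UNSAT",
        Rcpp::Named("model") = R_NilValue,
        Rcpp::Named("conflicts") = (double)S.conflicts,
        Rcpp::Named("decisions") = (double)S.decisions);
}
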