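// Exhaustive, isomorphism-free enumeration of bounded directed
// multigraph topologies (multiplicity-capped adjacency matrices), with
// canonical forms computed as the lexicographic minimum over all node
// permutations. Small-n by design: the feasibility searches this
// package runs never need more than a handful of compartments.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <functional>
#include <climits>
#include <cmath>

namespace {

// serialize multiplicity matrix under permutation perm (perm[i] = new
// position of node i): entry (i,j) -> (perm[i], perm[j])
std::string canon_string(const std::vector<int> &m, int n,
                         const std::vector<std::vector<int> > &perms) {
    std::string best;
    std::string cur(n * n, '0');
    for (size_t p = 0; p < perms.size(); p++) {
        const std::vector<int> &pp = perms[p];
        for (int i = 0; i < n; i++)
            for (int j = 0; j < n; j++)
                cur[pp[i] * n + pp[j]] = (char)('0' + m[i * n + j]);
        if (best.empty() || cur < best) best = cur;
    }
    return best;
}

std::string self_string(const std::vector<int> &m, int n) {
    std::string s(n * n, '0');
    for (int i = 0; i < n * n; i++) s[i] = (char)('0' + m[i]);
    return s;
}

bool strongly_connected(const std::vector<int> &m, int n) {
    // reachability closure
    std::vector<unsigned char> r(n * n, 0);
    for (int i = 0; i < n; i++) r[i * n + i] = 1;
    for (int i = 0; i < n; i++)
        for (int j = 0; j < n; j++)
            if (m[i * n + j] > 0) r[i * n + j] = 1;
    for (int k = 0; k < n; k++)
        for (int i = 0; i < n; i++)
            for (int j = 0; j < n; j++)
                if (r[i * n + k] && r[k * n + j]) r[i * n + j] = 1;
    for (int i = 0; i < n * n; i++) if (!r[i]) return false;
    return true;
}

// undirected multigraph edge connectivity by subset enumeration
int underlying_connectivity(const std::vector<int> &m, int n) {
    if (n == 1) return INT_MAX;
    int best = INT_MAX;
    // node 0 always on the S side (complement symmetry); mask over the
    // remaining nodes, excluding the all-ones mask (S must be proper)
    for (int mask = 0; mask < (1 << (n - 1)) - 1; mask++) {
        int cut = 0;
        for (int i = 0; i < n; i++) {
            bool si = (i == 0) || (mask & (1 << (i - 1)));
            for (int j = 0; j < n; j++) {
                bool sj = (j == 0) || (mask & (1 << (j - 1)));
                if (si && !sj) cut += m[i * n + j] + m[j * n + i];
            }
        }
        if (cut < best) best = cut;
    }
    return best;
}

} // namespace

// [[Rcpp::export(name = ".topo_enum_cpp")]]
Rcpp::List topo_enum_cpp(int n, int cap, int edge_budget) {
    if (n < 1 || n > 6) Rcpp::stop("node count must be between 1 and 6");
    if (cap < 1) Rcpp::stop("multiplicity cap must be >= 1");
    int npairs = n * (n - 1);
    // refuse search spaces that cannot be enumerated exhaustively
    double space = std::pow((double)(cap + 1), (double)npairs);
    if (edge_budget < 0 && space > 2e6 && n > 4)
        Rcpp::stop("search space too large for exhaustive enumeration; "
                   "supply an edge budget");

    std::vector<std::vector<int> > perms;
    {
        std::vector<int> p(n);
        for (int i = 0; i < n; i++) p[i] = i;
        do { perms.push_back(p); } while (std::next_permutation(p.begin(), p.end()));
    }

    std::vector<std::pair<int, int> > pairs;
    for (int i = 0; i < n; i++)
        for (int j = 0; j < n; j++)
            if (i != j) pairs.push_back(std::make_pair(i, j));

    std::vector<int> m(n * n, 0);
    std::vector<Rcpp::IntegerMatrix> out;
    std::vector<std::string> certs;
    std::vector<int> conns;
    std::vector<int> strongs;

    // DFS over ordered pairs
    std::vector<int> stack_mult(npairs, 0);
    long long visited = 0;
    std::function<void(int, int)> rec = [&](int idx, int total) {
        if (edge_budget >= 0 && total > edge_budget) return;
        if (idx == npairs) {
            visited++;
            if ((visited & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
            std::string self = self_string(m, n);
            std::string canon = canon_string(m, n, perms);
            if (self != canon) return;   // emit canonical representatives only
            Rcpp::IntegerMatrix mm(n, n);
            for (int i = 0; i < n; i++)
                for (int j = 0; j < n; j++)
                    mm(i, j) = m[i * n + j];
            out.push_back(mm);
            certs.push_back(canon);
            conns.push_back(underlying_connectivity(m, n) == INT_MAX
                                ? NA_INTEGER
                                : underlying_connectivity(m, n));
            strongs.push_back(strongly_connected(m, n) ? 1 : 0);
            return;
        }
        for (int v = 0; v <= cap; v++) {
            m[pairs[idx].first * n + pairs[idx].second] = v;
            rec(idx + 1, total + v);
        }
        m[pairs[idx].first * n + pairs[idx].second] = 0;
    };
    rec(0, 0);

    // deterministic order: lexicographic by certificate
    std::vector<size_t> ord(out.size());
    for (size_t i = 0; i < ord.size(); i++) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](size_t a, size_t b) { return certs[a] < certs[b]; });

    Rcpp::List mats(out.size());
    Rcpp::CharacterVector cv(out.size());
    Rcpp::IntegerVector connv(out.size()), strongv(out.size());
    for (size_t i = 0; i < ord.size(); i++) {
        mats[i] = out[ord[i]];
        cv[i] = certs[ord[i]];
        connv[i] = conns[ord[i]];
        strongv[i] = strongs[ord[i]];
    }
    return Rcpp::List::create(Rcpp::Named("matrices") = mats,
                              Rcpp::Named("certificate") = cv,
                              Rcpp::Named("connectivity") = connv,
                              Rcpp::Named("strong") = strongv);
}

// [[Rcpp::export(name = ".topo_canon_cpp")]]
Rcpp::String topo_canon_cpp(Rcpp::IntegerMatrix mult) {
    int n = mult.nrow();
    if (mult.ncol() != n) Rcpp::stop("multiplicity matrix must be square");
    if (n > 8) Rcpp::stop("canonical form supported for up to 8 nodes");
    std::vector<int> m(n * n);
    for (int i = 0; i < n; i++)
        for (int j = 0; j < n; j++) m[i * n + j] = mult(i, j);
    std::vector<std::vector<int> > perms;
    std::vector<int> p(n);
    for (int i = 0; i < n; i++) p[i] = i;
    do { perms.push_back(p); } while (std::next_permutation(p.begin(), p.end()));
    return canon_string(m, n, perms);
}
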