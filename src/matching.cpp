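#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One-to-one assignment of reference to target localizations within a
// distance tolerance: maximum cardinality first, then minimum total
// distance. Solved as a sparse assignment problem (Jonker-Volgenant style
// row-by-row shortest augmenting paths with dual potentials). Each row i
// owns a private virtual column (index m+i) of cost BIG so a complete
// row assignment always exists; rows assigned to their virtual column are
// unmatched. BIG dominates any sum of real distances, so minimizing total
// cost maximizes the number of real pairs.

static const double BIG = 1e9;
static const double EPS = 1e-9;

struct SparseAssign {
    int n, m;                                    // rows, real columns
    const std::vector<std::vector<std::pair<int, double> > >& adj;
    std::vector<double> u, v;                    // dual potentials
    std::vector<int> matchCol;                   // col -> row (-1 free)
    std::vector<int> matchRow;                   // row -> col

    SparseAssign(int n_, int m_,
                 const std::vector<std::vector<std::pair<int, double> > >& adj_)
        : n(n_), m(m_), adj(adj_), u(n_, 0.0), v(m_ + n_, 0.0),
          matchCol(m_ + n_, -1), matchRow(n_, -1) {}

    double edgeCost(int i, int j) const {
        if (j >= m) return (j == m + i) ? BIG : R_PosInf;
        for (size_t k = 0; k < adj[i].size(); ++k)
            if (adj[i][k].first == j) return adj[i][k].second;
        return R_PosInf;
    }

    void relaxRow(int i, double base,
                  std::vector<double>& dist, std::vector<int>& prevRow,
                  std::vector<char>& done,
                  std::priority_queue<std::pair<double, int>,
                                      std::vector<std::pair<double, int> >,
                                      std::greater<std::pair<double, int> > >& pq,
                  std::vector<int>& touched) {
        for (size_t k = 0; k < adj[i].size(); ++k) {
            int j = adj[i][k].first;
            if (done[j]) continue;
            double nd = base + adj[i][k].second - u[i] - v[j];
            if (nd < dist[j] - EPS) {
                if (dist[j] == R_PosInf) touched.push_back(j);
                dist[j] = nd;
                prevRow[j] = i;
                pq.push(std::make_pair(nd, j));
            }
        }
        int jv = m + i;  // virtual column of row i
        if (!done[jv]) {
            double nd = base + BIG - u[i] - v[jv];
            if (nd < dist[jv] - EPS) {
                if (dist[jv] == R_PosInf) touched.push_back(jv);
                dist[jv] = nd;
                prevRow[jv] = i;
                pq.push(std::make_pair(nd, jv));
            }
        }
    }

    void solve() {
        int ncol = m + n;
        std::vector<double> dist(ncol, R_PosInf), dfin(ncol, 0.0);
        std::vector<int> prevRow(ncol, -1);
        std::vector<char> done(ncol, 0);
        std::vector<int> touched;

        for (int s = 0; s < n; ++s) {
            std::priority_queue<std::pair<double, int>,
                                std::vector<std::pair<double, int> >,
                                std::greater<std::pair<double, int> > > pq;
            touched.clear();
            std::vector<int> finalized;
            relaxRow(s, 0.0, dist, prevRow, done, pq, touched);

            int jf = -1;
            double D = 0.0;
            while (!pq.empty()) {
                std::pair<double, int> top = pq.top(); pq.pop();
                int j = top.second;
                if (done[j] || top.first > dist[j] + EPS) continue;
                done[j] = 1;
                dfin[j] = dist[j];
                finalized.push_back(j);
                if (matchCol[j] == -1) { jf = j; D = dist[j]; break; }
                relaxRow(matchCol[j], dist[j], dist, prevRow, done, pq, touched);
            }
            // jf always found: the virtual column of s is reachable and free
            for (size_t k = 0; k < finalized.size(); ++k) {
                int j = finalized[k];
                if (j == jf) continue;
                v[j] -= (D - dfin[j]);
                u[matchCol[j]] += (D - dfin[j]);
            }
            u[s] += D;
            // augment along the alternating path
            int j = jf;
            while (true) {
                int i = prevRow[j];
                int jprev = matchRow[i];
                matchCol[j] = i;
                matchRow[i] = j;
                if (i == s) break;
                j = jprev;
            }
            for (size_t k = 0; k < touched.size(); ++k) {
                int j2 = touched[k];
                dist[j2] = R_PosInf; prevRow[j2] = -1; done[j2] = 0;
            }
        }
    }
};

static void buildAdj(const NumericMatrix& ref, const NumericMatrix& tgt,
                     double tol,
                     std::vector<std::vector<std::pair<int, double> > >& adj) {
    int n = ref.nrow(), m = tgt.nrow();
    adj.assign(n, std::vector<std::pair<int, double> >());
    double tol2 = tol * tol;
    for (int i = 0; i < n; ++i) {
        for (int j = 0; j < m; ++j) {
            double dx = ref(i, 0) - tgt(j, 0);
            double dy = ref(i, 1) - tgt(j, 1);
            double d2 = dx * dx + dy * dy;
            if (d2 <= tol2) adj[i].push_back(std::make_pair(j, std::sqrt(d2)));
        }
    }
}

// [[Rcpp::export]]
IntegerVector cpp_match_pairs(NumericMatrix ref, NumericMatrix tgt, double tol) {
    int n = ref.nrow(), m = tgt.nrow();
    IntegerVector out(n, NA_INTEGER);
    if (n == 0 || m == 0) return out;
    std::vector<std::vector<std::pair<int, double> > > adj;
    buildAdj(ref, tgt, tol, adj);
    SparseAssign sa(n, m, adj);
    sa.solve();
    for (int i = 0; i < n; ++i)
        if (sa.matchRow[i] >= 0 && sa.matchRow[i] < m) out[i] = sa.matchRow[i] + 1;
    return out;
}

// Matched-pair counts for each tolerance of an ascending grid; each
// tolerance is an independent assignment solve.
// [[Rcpp::export]]
IntegerVector cpp_match_counts(NumericMatrix ref, NumericMatrix tgt,
                               NumericVector tgrid) {
    int n = ref.nrow(), m = tgt.nrow(), nt = tgrid.size();
    IntegerVector out(nt, 0);
    if (n == 0 || m == 0) return out;
    // precompute all pairwise distances once
    std::vector<std::vector<std::pair<int, double> > > all;
    double tmax = tgrid[nt - 1];
    buildAdj(ref, tgt, tmax, all);
    for (int k = 0; k < nt; ++k) {
        double t = tgrid[k];
        std::vector<std::vector<std::pair<int, double> > > adj(n);
        for (int i = 0; i < n; ++i)
            for (size_t e = 0; e < all[i].size(); ++e)
                if (all[i][e].second <= t) adj[i].push_back(all[i][e]);
        SparseAssign sa(n, m, adj);
        sa.solve();
        int cnt = 0;
        for (int i = 0; i < n; ++i)
            if (sa.matchRow[i] >= 0 && sa.matchRow[i] < m) ++cnt;
        out[k] = cnt;
    }
    return out;
}
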