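#include <Rcpp.h>
#include <vector>
#include <map>
#include <limits>
using namespace Rcpp;

// Shortest-augmenting-path Hungarian algorithm on a dense square matrix
// (row-major, size n x n). Returns, for each row, the assigned column
// (0-based). The matrix must admit a finite-cost perfect matching.
static std::vector<int> hungarian_square(const std::vector<double>& a, int n) {
    const double INF = std::numeric_limits<double>::infinity();
    std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
    std::vector<int> p(n + 1, 0), way(n + 1, 0);
    for (int i = 1; i <= n; ++i) {
        p[0] = i;
        int j0 = 0;
        std::vector<double> minv(n + 1, INF);
        std::vector<char> used(n + 1, 0);
        do {
            used[j0] = 1;
            int i0 = p[j0], j1 = -1;
            double delta = INF;
            for (int j = 1; j <= n; ++j) {
                if (used[j]) continue;
                double cur = a[(size_t)(i0 - 1) * n + (j - 1)] - u[i0] - v[j];
                if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
                if (minv[j] < delta) { delta = minv[j]; j1 = j; }
            }
            for (int j = 0; j <= n; ++j) {
                if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
                else minv[j] -= delta;
            }
            j0 = j1;
        } while (p[j0] != 0);
        do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0 != 0);
    }
    std::vector<int> row_to_col(n, -1);
    for (int j = 1; j <= n; ++j)
        if (p[j] > 0) row_to_col[p[j] - 1] = j - 1;
    return row_to_col;
}

struct DSU {
    std::vector<int> parent;
    DSU(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
    int find(int x) { while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; } return x; }
    void unite(int a, int b) { a = find(a); b = find(b); if (a != b) parent[b] = a; }
};

// One-to-one partial matching between the rows and columns of `cost`,
// minimizing  sum(linked costs) + dummy_cost * (number of unmatched rows
// and columns).  Entries with cost > gate (or non-finite) can never be
// linked.  Decomposes the admissibility graph into connected components
// and solves an augmented square assignment problem per component, so the
// cost is near-linear for the sparse gating typical of particle linking.
//
// Returns match: integer vector of length nrow, 1-based column index or
// 0 for unmatched; and the total objective value.
// [[Rcpp::export]]
List gated_assignment_cpp(NumericMatrix cost, double gate, double dummy_cost) {
    const double BIG = 1e15;
    int n = cost.nrow(), m = cost.ncol();
    IntegerVector match(n);
    std::fill(match.begin(), match.end(), 0);

    DSU dsu(n + m);
    std::vector<char> row_has(n, 0), col_has(m, 0);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < m; ++j) {
            double c = cost(i, j);
            if (R_finite(c) && c <= gate) {
                dsu.unite(i, n + j);
                row_has[i] = 1;
                col_has[j] = 1;
            }
        }

    // group rows/cols that participate in at least one admissible pair
    std::map<int, std::pair<std::vector<int>, std::vector<int> > > comps;
    for (int i = 0; i < n; ++i)
        if (row_has[i]) comps[dsu.find(i)].first.push_back(i);
    for (int j = 0; j < m; ++j)
        if (col_has[j]) comps[dsu.find(n + j)].second.push_back(j);

    double total = 0.0;
    for (std::map<int, std::pair<std::vector<int>, std::vector<int> > >::iterator
             it = comps.begin(); it != comps.end(); ++it) {
        std::vector<int>& R = it->second.first;
        std::vector<int>& C = it->second.second;
        int nr = (int)R.size(), nc = (int)C.size();
        int k = nr + nc;
        std::vector<double> a((size_t)k * k, BIG);
        for (int ii = 0; ii < nr; ++ii)
            for (int jj = 0; jj < nc; ++jj) {
                double c = cost(R[ii], C[jj]);
                if (R_finite(c) && c <= gate) a[(size_t)ii * k + jj] = c;
            }
        for (int ii = 0; ii < nr; ++ii)            // row i <-> its own dummy col
            a[(size_t)ii * k + (nc + ii)] = dummy_cost;
        for (int jj = 0; jj < nc; ++jj)            // col j's dummy row
            a[(size_t)(nr + jj) * k + jj] = dummy_cost;
        for (int ii = 0; ii < nc; ++ii)            // dummy-dummy corner: free
            for (int jj = 0; jj < nr; ++jj)
                a[(size_t)(nr + ii) * k + (nc + jj)] = 0.0;

        std::vector<int> rc = hungarian_square(a, k);
        for (int ii = 0; ii < nr; ++ii) {
            int j = rc[ii];
            if (j >= 0 && j < nc) {
                match[R[ii]] = C[j] + 1;
                total += cost(R[ii], C[j]);
            } else {
                total += dummy_cost;               // row left unmatched
            }
        }
        for (int jj = 0; jj < nc; ++jj) {          // columns left unmatched
            bool taken = false;
            for (int ii = 0; ii < nr; ++ii)
                if (rc[ii] == jj) { taken = true; break; }
            if (!taken) total += dummy_cost;
        }
    }
    // rows/cols with no admissible partner at all
    for (int i = 0; i < n; ++i) if (!row_has[i]) total += dummy_cost;
    for (int j = 0; j < m; ++j) if (!col_has[j]) total += dummy_cost;

    return List::create(_["match"] = match, _["total_cost"] = total);
}

// 2D convolution with replicate (edge-clamp) border handling.
// Kernel dimensions must be odd.
// [[Rcpp::export]]
NumericMatrix conv2_replicate(NumericMatrix img, NumericMatrix kernel) {
    int nr = img.nrow(), nc = img.ncol();
    int kr = kernel.nrow(), kc = kernel.ncol();
    if (kr % 2 == 0 || kc % 2 == 0) stop("kernel dimensions must be odd");
    if (nr < 1 || nc < 1) stop("empty image");
    int hr = kr / 2, hc = kc / 2;
    NumericMatrix out(nr, nc);
    for (int i = 0; i < nr; ++i) {
        for (int j = 0; j < nc; ++j) {
            double s = 0.0;
            for (int di = -hr; di <= hr; ++di) {
                int ii = i + di;
                if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
                for (int dj = -hc; dj <= hc; ++dj) {
                    int jj = j + dj;
                    if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
                    s += img(ii, jj) * kernel(di + hr, dj + hc);
                }
            }
            out(i, j) = s;
        }
    }
    return out;
}
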