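#include <Rcpp.h>
using namespace Rcpp;

// A "probe" is one examination of a stored row index against the requested
// row (a three-way comparison). Every read of i[k] during a lookup counts as
// exactly one probe, in both the naive and cached paths, so the two counters
// are directly comparable and hardware-independent.

namespace {

// lower bound of r in i[lo, hi), counting one probe per examined index
inline int lb_probe(const int* idx, int lo, int hi, int r, double& probes) {
    while (lo < hi) {
        int mid = lo + (hi - lo) / 2;
        probes += 1;
        if (idx[mid] < r) lo = mid + 1; else hi = mid;
    }
    return lo;
}

struct CSC {
    const double* x;
    const int* i;
    const int* p;
};

// Serve row r (0-based) for column c through the cache state. ptr[c] holds
// the lower bound of the previously served row within column c; last_row < 0
// means no history. Leaves ptr[c] at the lower bound of r.
inline double serve_cached(const CSC& m, int c, int r, int last_row,
                           int* ptr, double& probes) {
    const int lo = m.p[c], hi = m.p[c + 1];
    int pos;
    bool examined = false;  // whether i[pos] vs r is already known
    double hit = 0.0;
    if (last_row < 0) {
        pos = lb_probe(m.i, lo, hi, r, probes);
    } else if (r == last_row) {
        pos = ptr[c];
    } else if (r == last_row + 1) {
        pos = ptr[c];
        while (pos < hi) {
            probes += 1;
            if (m.i[pos] >= r) { examined = true; break; }
            ++pos;
        }
        if (examined && m.i[pos] == r) hit = m.x[pos];
    } else if (r > last_row) {
        pos = lb_probe(m.i, ptr[c], hi, r, probes);
    } else {  // r < last_row: everything at or past ptr[c] is >= last_row > r
        pos = lb_probe(m.i, lo, ptr[c], r, probes);
    }
    if (!examined && pos < hi) {
        probes += 1;
        if (m.i[pos] == r) hit = m.x[pos];
    }
    ptr[c] = pos;
    return hit;
}

inline double serve_naive(const CSC& m, int c, int r, double& probes) {
    int pos = lb_probe(m.i, m.p[c], m.p[c + 1], r, probes);
    if (pos < m.p[c + 1]) {
        probes += 1;
        if (m.i[pos] == r) return m.x[pos];
    }
    return 0.0;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_csc_row_naive")]]
List cpp_csc_row_naive(NumericVector x, IntegerVector i, IntegerVector p,
                       int r, int first, int last) {
    // r, first 0-based; [first, last) half-open column range
    CSC m{REAL(x), INTEGER(i), INTEGER(p)};
    NumericVector out(last - first);
    double probes = 0;
    for (int c = first; c < last; ++c) {
        out[c - first] = serve_naive(m, c, r, probes);
    }
    return List::create(_["values"] = out, _["probes"] = probes);
}

// [[Rcpp::export(name = ".cpp_csc_row_cached")]]
List cpp_csc_row_cached(NumericVector x, IntegerVector i, IntegerVector p,
                        int r, int first, int last,
                        IntegerVector ptr, int last_row) {
    CSC m{REAL(x), INTEGER(i), INTEGER(p)};
    IntegerVector newptr = clone(ptr);
    NumericVector out(last - first);
    double probes = 0;
    for (int c = first; c < last; ++c) {
        out[c - first] = serve_cached(m, c, r, last_row, INTEGER(newptr), probes);
    }
    return List::create(_["values"] = out, _["probes"] = probes,
                        _["ptr"] = newptr);
}

// Full sweep over the rows listed in `order` (0-based), visiting every
// column of each row. Returns the per-row sums (for cheap equivalence
// checks against an oracle) and the total probe count.

// [[Rcpp::export(name = ".cpp_csc_sweep_naive")]]
List cpp_csc_sweep_naive(NumericVector x, IntegerVector i, IntegerVector p,
                         int ncol, IntegerVector order) {
    CSC m{REAL(x), INTEGER(i), INTEGER(p)};
    const int nvisit = order.size();
    NumericVector rowtot(nvisit);
    double probes = 0;
    for (int k = 0; k < nvisit; ++k) {
        const int r = order[k];
        double tot = 0;
        for (int c = 0; c < ncol; ++c) tot += serve_naive(m, c, r, probes);
        rowtot[k] = tot;
    }
    return List::create(_["row_totals"] = rowtot, _["probes"] = probes);
}

// [[Rcpp::export(name = ".cpp_csc_sweep_cached")]]
List cpp_csc_sweep_cached(NumericVector x, IntegerVector i, IntegerVector p,
                          int ncol, IntegerVector order) {
    CSC m{REAL(x), INTEGER(i), INTEGER(p)};
    const int nvisit = order.size();
    NumericVector rowtot(nvisit);
    std::vector<int> ptr(ncol);
    for (int c = 0; c < ncol; ++c) ptr[c] = p[c + 1];
    int last_row = -1;
    double probes = 0;
    for (int k = 0; k < nvisit; ++k) {
        const int r = order[k];
        double tot = 0;
        for (int c = 0; c < ncol; ++c) {
            tot += serve_cached(m, c, r, last_row, ptr.data(), probes);
        }
        last_row = r;
        rowtot[k] = tot;
    }
    return List::create(_["row_totals"] = rowtot, _["probes"] = probes);
}
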