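#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Exact branch-and-bound for small 0/1 programs:
//   maximize c'x  subject to  A x <= b,  x binary,
// with A given sparsely per constraint. Depth-first search in variable
// order, 1-branch first; the bound is the current value plus the positive
// part of the unfixed objective. Feasibility is maintained incrementally:
// a node is pruned when a row's accumulated left-hand side minus the
// negative coefficients still pending on unfixed variables exceeds the
// right-hand side. The search is complete, so a returned solution is a
// proven optimum; if the node budget is exhausted the caller gets a
// "node_limit" status and no incumbent is reported as optimal.

namespace {

struct Problem {
    int n;
    std::vector<double> obj;
    // per-variable sparse column: (row, coef)
    std::vector<std::vector<std::pair<int, double>>> colrow;
    std::vector<double> rhs;
};

struct Search {
    const Problem* p;
    std::vector<double> acc;     // accumulated LHS per row (fixed vars)
    std::vector<double> negpend; // sum of negative coefs on unfixed vars
    std::vector<double> sufpos;  // suffix sum of positive objective
    std::vector<int> x, bestx;
    double cur = 0.0, best = 0.0;
    bool have_best = false;
    int64_t nodes = 0, node_limit;
    bool aborted = false;

    bool feasible_rows(const std::vector<int>& rows) const {
        for (int r : rows)
            if (acc[r] + negpend[r] > p->rhs[r] + 1e-9) return false;
        return true;
    }

    void dfs(int v) {
        if (aborted) return;
        if (++nodes > node_limit) { aborted = true; return; }
        if (v == p->n) {
            if (!have_best || cur > best + 1e-9) {
                best = cur;
                bestx = x;
                have_best = true;
            }
            return;
        }
        if (have_best && cur + sufpos[v] <= best + 1e-9) return;
        // branch x_v = 1
        bool ok = true;
        for (const auto& rc : p->colrow[v]) {
            acc[rc.first] += rc.second;
            if (rc.second < 0) negpend[rc.first] -= rc.second;
            if (acc[rc.first] + negpend[rc.first] > p->rhs[rc.first] + 1e-9)
                ok = false;
        }
        if (ok) {
            x[v] = 1;
            cur += p->obj[v];
            dfs(v + 1);
            cur -= p->obj[v];
        }
        for (const auto& rc : p->colrow[v]) {
            acc[rc.first] -= rc.second;
            if (rc.second < 0) negpend[rc.first] += rc.second;
        }
        // branch x_v = 0: only pending negatives change
        bool ok0 = true;
        for (const auto& rc : p->colrow[v])
            if (rc.second < 0) negpend[rc.first] -= rc.second;
        for (const auto& rc : p->colrow[v])
            if (acc[rc.first] + negpend[rc.first] > p->rhs[rc.first] + 1e-9)
                ok0 = false;
        if (ok0) {
            x[v] = 0;
            dfs(v + 1);
        }
        for (const auto& rc : p->colrow[v])
            if (rc.second < 0) negpend[rc.first] += rc.second;
    }
};

} // namespace

// con_idx: list of integer vectors (1-based variable indices per constraint);
// con_coef: matching coefficient vectors; rhs: right-hand sides.
// [[Rcpp::export]]
List cpp_bnb(NumericVector obj, List con_idx, List con_coef,
             NumericVector rhs, double node_limit = 5e7) {
    Problem p;
    p.n = obj.size();
    p.obj.assign(obj.begin(), obj.end());
    p.rhs.assign(rhs.begin(), rhs.end());
    p.colrow.assign(p.n, {});
    int m = con_idx.size();
    std::vector<double> negsum(m, 0.0);
    for (int r = 0; r < m; ++r) {
        IntegerVector idx = con_idx[r];
        NumericVector coef = con_coef[r];
        for (int t = 0; t < idx.size(); ++t) {
            p.colrow[idx[t] - 1].push_back({r, coef[t]});
            if (coef[t] < 0) negsum[r] += coef[t];
        }
    }
    Search s;
    s.p = &p;
    s.acc.assign(m, 0.0);
    s.negpend = negsum;
    s.x.assign(p.n, 0);
    s.node_limit = (int64_t)node_limit;
    s.sufpos.assign(p.n + 1, 0.0);
    for (int v = p.n - 1; v >= 0; --v)
        s.sufpos[v] = s.sufpos[v + 1] + std::max(p.obj[v], 0.0);
    s.dfs(0);
    std::string status;
    if (s.aborted) status = "node_limit";
    else if (!s.have_best) status = "infeasible";
    else status = "optimal";
    IntegerVector xv(p.n);
    if (s.have_best)
        for (int v = 0; v < p.n; ++v) xv[v] = s.bestx[v];
    return List::create(_["status"] = status,
                        _["objective"] = s.have_best ? s.best : NA_REAL,
                        _["x"] = xv,
                        _["nodes"] = (double)s.nodes);
}
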