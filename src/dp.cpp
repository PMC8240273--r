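#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Exact subset dynamic program for the longest run subsequence.
//
// State: D[i, F] = best total length of a valid run subsequence of r_1..r_i
// that ends with r_i selected and uses exactly the symbols in F. Column 0 is
// a virtual start (D[0, empty] = 0). Transitions follow the predecessor sets
// R(i): the last occurrence P_sigma(i) of every symbol sigma (plus the
// virtual start at 0) at or after P_{sigma(r_i)}(i). A predecessor j with the
// same symbol extends the current run (F unchanged); a different symbol opens
// a new run (F gains sigma(r_i), which must be fresh on that path).
//
// Two storages produce identical tables: a dense flat array when
// (n + 1) * 2^|Sigma| fits a fixed memory guard, and a sparse push-style
// hash map of reachable (mask -> entry) states per column otherwise.
//
// Tie-breaks (deterministic co-optimum): among predecessors attaining the
// max, the smallest j; among global maxima, the smallest i, then the
// numerically smallest mask.

namespace {

struct Entry {
    int64_t val;
    int32_t pred;
};

// Predecessor sets R(i), 0-based runs; entries are 0..i (0 = virtual start,
// j>0 meaning run j). Returned sorted ascending.
std::vector<std::vector<int>> predecessor_sets(const std::vector<int>& sym,
                                               int n, int nsym) {
    std::vector<int> lastocc(nsym, 0); // 1-based run index, 0 = absent
    std::vector<std::vector<int>> R(n);
    for (int i = 0; i < n; ++i) {
        int thresh = lastocc[sym[i]];
        std::vector<int> r;
        if (thresh == 0) r.push_back(0); // virtual start admissible
        for (int s = 0; s < nsym; ++s)
            if (lastocc[s] >= std::max(thresh, 1)) r.push_back(lastocc[s]);
        std::sort(r.begin(), r.end());
        r.erase(std::unique(r.begin(), r.end()), r.end());
        R[i] = r;
        lastocc[sym[i]] = i + 1;
    }
    return R;
}

} // namespace

// [[Rcpp::export]]
List cpp_solve_dp(IntegerVector sym0, IntegerVector len, int nsym,
                  double dense_limit_bytes = 1.5e9) {
    int n = sym0.size();
    if (n == 0)
        return List::create(_["indices"] = IntegerVector(0),
                            _["optimum"] = 0.0);
    std::vector<int> sym(sym0.begin(), sym0.end());
    std::vector<std::vector<int>> R = predecessor_sets(sym, n, nsym);

    const uint64_t nmask = 1ULL << nsym;
    const double dense_bytes =
        (double)(n + 1) * (double)nmask * (double)sizeof(Entry);
    const int64_t NEG = INT64_MIN / 4;

    int best_i = -1;
    uint32_t best_mask = 0;
    int64_t best_val = -1;
    std::vector<int> chosen;

    if (dense_bytes <= dense_limit_bytes) {
        // Dense pull-style table.
        std::vector<Entry> D((size_t)(n + 1) * nmask, Entry{NEG, -1});
        D[0].val = 0; // column 0, empty mask
        for (int i = 1; i <= n; ++i) {
            const uint32_t bit = 1u << sym[i - 1];
            const size_t row = (size_t)i * nmask;
            for (uint32_t F = 0; F < nmask; ++F) {
                if (!(F & bit)) continue;
                int64_t best = NEG;
                int32_t arg = -1;
                for (int j : R[i - 1]) {
                    int64_t v;
                    if (j > 0 && sym[j - 1] == sym[i - 1])
                        v = D[(size_t)j * nmask + F].val;
                    else
                        v = D[(size_t)j * nmask + (F & ~bit)].val;
                    if (v > best) { best = v; arg = j; }
                }
                if (best > NEG) {
                    D[row + F].val = best + len[i - 1];
                    D[row + F].pred = arg;
                }
            }
        }
        for (int i = 1; i <= n; ++i)
            for (uint32_t F = 0; F < nmask; ++F) {
                int64_t v = D[(size_t)i * nmask + F].val;
                if (v > best_val && v > NEG) {
                    best_val = v; best_i = i; best_mask = F;
                }
            }
        if (best_i >= 0) {
            int i = best_i;
            uint32_t F = best_mask;
            while (i > 0) {
                chosen.push_back(i);
                int j = D[(size_t)i * nmask + F].pred;
                if (!(j > 0 && sym[j - 1] == sym[i - 1]))
                    F &= ~(1u << sym[i - 1]);
                i = j;
            }
        }
    } else {
        // Sparse push-style columns over reachable masks only.
        // Successor lists invert the predecessor sets.
        std::vector<std::vector<int>> succ(n + 1);
        for (int i = 0; i < n; ++i)
            for (int j : R[i]) succ[j].push_back(i + 1);
        std::vector<std::unordered_map<uint32_t, Entry>> col(n + 1);
        col[0][0] = Entry{0, -1};
        for (int j = 0; j <= n; ++j) {
            for (const auto& kv : col[j]) {
                const uint32_t Fj = kv.first;
                const int64_t vj = kv.second.val;
                for (int i : succ[j]) {
                    const uint32_t bit = 1u << sym[i - 1];
                    uint32_t Ft;
                    if (j > 0 && sym[j - 1] == sym[i - 1]) {
                        Ft = Fj; // extend the same run
                    } else {
                        if (Fj & bit) continue; // symbol already closed
                        Ft = Fj | bit;
                    }
                    int64_t nv = vj + len[i - 1];
                    auto it = col[i].find(Ft);
                    // strict improvement keeps the smallest predecessor j
                    if (it == col[i].end() || nv > it->second.val)
                        col[i][Ft] = Entry{nv, (int32_t)j};
                }
            }
        }
        for (int i = 1; i <= n; ++i)
            for (const auto& kv : col[i]) {
                if (kv.second.val > best_val ||
                    (kv.second.val == best_val && i == best_i &&
                     kv.first < best_mask)) {
                    // columns scanned ascending: first i attaining the max
                    // wins; within a column the smallest mask wins
                    if (kv.second.val > best_val) {
                        best_val = kv.second.val; best_i = i;
                        best_mask = kv.first;
                    } else {
                        best_mask = kv.first;
                    }
                }
            }
        if (best_i >= 0) {
            int i = best_i;
            uint32_t F = best_mask;
            while (i > 0) {
                chosen.push_back(i);
                int j = col[i][F].pred;
                if (!(j > 0 && sym[j - 1] == sym[i - 1]))
                    F &= ~(1u << sym[i - 1]);
                i = j;
            }
        }
    }

    std::sort(chosen.begin(), chosen.end());
    IntegerVector idx(chosen.size());
    for (size_t t = 0; t < chosen.size(); ++t) idx[t] = chosen[t];
    return List::create(_["indices"] = idx,
                        _["optimum"] = (double)(best_val < 0 ? 0 : best_val));
}
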