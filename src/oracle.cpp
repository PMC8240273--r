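#include <Rcpp.h>
#include "common.h"
using namespace Rcpp;

// Brute-force reference solver: enumerate all 2^n run subsets, keep the
// valid ones, return a maximum-total-length selection. Ties are broken by
// the lexicographically smallest index sequence. Caller enforces the run
// cap; n <= 30 keeps the mask in an int64.
// [[Rcpp::export]]
IntegerVector cpp_bruteforce(IntegerVector sym0, IntegerVector len, int nsym) {
    int n = sym0.size();
    std::vector<int> sym(sym0.begin(), sym0.end());
    std::vector<char> buf;
    std::vector<int> cur, best;
    long long best_len = 0; // empty selection is always valid
    const uint64_t lim = 1ULL << n;
    for (uint64_t mask = 0; mask < lim; ++mask) {
        cur.clear();
        long long tot = 0;
        for (int i = 0; i < n; ++i) {
            if (mask & (1ULL << i)) {
                cur.push_back(i);
                tot += len[i];
            }
        }
        if (tot < best_len) continue;
        if (!valid_core(sym, nsym, cur.data(), (int)cur.size(), buf)) continue;
        if (tot > best_len ||
            (tot == best_len &&
             std::lexicographical_compare(cur.begin(), cur.end(),
                                          best.begin(), best.end()))) {
            best_len = tot;
            best = cur;
        }
    }
    IntegerVector out(best.size());
    for (size_t t = 0; t < best.size(); ++t) out[t] = best[t] + 1;
    return out;
}
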