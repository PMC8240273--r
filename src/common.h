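#ifndef LRSOLVE_COMMON_H
#define LRSOLVE_COMMON_H

#include <vector>
#include <cstdint>

// Shared validity check for a run selection. `sym` holds the 0-based symbol
// id of every run; `sel` holds 0-based run indices in strictly increasing
// order. A selection is valid iff the induced subsequence has at most one
// maximal run per symbol: same-symbol selected runs separated only by
// unselected runs merge and are legal.
inline bool valid_core(const std::vector<int>& sym, int nsym,
                       const int* sel, int k,
                       std::vector<char>& seen_buf) {
    if ((int)seen_buf.size() < nsym) seen_buf.assign(nsym, 0);
    std::fill(seen_buf.begin(), seen_buf.end(), 0);
    int last = -1;
    for (int t = 0; t < k; ++t) {
        int s = sym[sel[t]];
        if (s == last) continue;       // extends the current merged run
        if (seen_buf[s]) return false; // symbol re-opened after closing
        seen_buf[s] = 1;
        last = s;
    }
    return true;
}

#endif
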