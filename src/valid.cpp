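#include <Rcpp.h>
#include "common.h"
using namespace Rcpp;

// sym0: 0-based symbol id per run; sel0: 0-based selected run indices,
// strictly increasing; nsym: alphabet size.
// [[Rcpp::export]]
bool cpp_is_valid(IntegerVector sym0, IntegerVector sel0, int nsym) {
    std::vector<int> sym(sym0.begin(), sym0.end());
    std::vector<int> sel(sel0.begin(), sel0.end());
    std::vector<char> buf;
    return valid_core(sym, nsym, sel.data(), (int)sel.size(), buf);
}
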