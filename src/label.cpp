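#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of the nonzero pixels of a binary mask by
// iterative flood fill. conn = 4 or 8. Labels are 1..n in scan order.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const IntegerMatrix& mask, int conn) {
    int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix lab(nr, nc);
    const int dx8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
    const int dy8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
    int nn = (conn == 8) ? 8 : 4;
    std::vector<int> stack;
    int next = 0;
    for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
            if (mask(r, c) == 0 || lab(r, c) != 0) continue;
            ++next;
            lab(r, c) = next;
            stack.push_back(r + nr * c);
            while (!stack.empty()) {
                int i = stack.back(); stack.pop_back();
                int rr = i % nr, cc = i / nr;
                for (int k = 0; k < nn; ++k) {
                    int r2 = rr + dx8[k], c2 = cc + dy8[k];
                    if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
                    if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
                        lab(r2, c2) = next;
                        stack.push_back(r2 + nr * c2);
                    }
                }
            }
        }
    }
    return lab;
}
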