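#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Guo-Hall parallel thinning (two subiterations per pass), iterated to
// stability. Preserves connectivity of foreground and background, hence the
// pattern's Betti numbers. Neighbours: p2=N, p3=NE, p4=E, p5=SE, p6=S,
// p7=SW, p8=W, p9=NW with rows growing southwards.
// [[Rcpp::export]]
IntegerMatrix thin_guo_hall_cpp(const IntegerMatrix& mask) {
    int nr = mask.nrow(), nc = mask.ncol();
    std::vector<unsigned char> img((size_t)nr * nc);
    for (int i = 0; i < nr * nc; ++i) img[i] = mask[i] != 0;
    std::vector<int> kill;
    bool changed = true;
    auto at = [&](int r, int c) -> int {
        if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
        return img[(size_t)r + (size_t)nr * c];
    };
    while (changed) {
        changed = false;
        for (int sub = 0; sub < 2; ++sub) {
            kill.clear();
            for (int c = 0; c < nc; ++c) {
                for (int r = 0; r < nr; ++r) {
                    if (!img[(size_t)r + (size_t)nr * c]) continue;
                    int p2 = at(r - 1, c),     p3 = at(r - 1, c + 1);
                    int p4 = at(r, c + 1),     p5 = at(r + 1, c + 1);
                    int p6 = at(r + 1, c),     p7 = at(r + 1, c - 1);
                    int p8 = at(r, c - 1),     p9 = at(r - 1, c - 1);
                    int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                            ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
                    if (C != 1) continue;
                    int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
                    int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
                    int N = N1 < N2 ? N1 : N2;
                    if (N < 2 || N > 3) continue;
                    int m = (sub == 0) ? ((p6 | p7 | (!p9)) & p8)
                                       : ((p2 | p3 | (!p5)) & p4);
                    if (m == 0) kill.push_back(r + nr * c);
                }
            }
            if (!kill.empty()) {
                changed = true;
                for (size_t i = 0; i < kill.size(); ++i) img[kill[i]] = 0;
            }
        }
    }
    IntegerMatrix out(nr, nc);
    for (int i = 0; i < nr * nc; ++i) out[i] = img[i];
    return out;
}
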