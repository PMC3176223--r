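#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Neighborhood shells by squared distance: order 1 = von Neumann (r2=1),
// order 2 = Moore (adds r2=2), order 3 adds r2=4, order 4 adds r2=5.
static void neigh_offsets(int order, std::vector<int>& dx, std::vector<int>& dy) {
    dx.clear(); dy.clear();
    const int sx[20] = { 1,-1, 0, 0,  1, 1,-1,-1,  2,-2, 0, 0,  2, 2,-2,-2, 1, 1,-1,-1};
    const int sy[20] = { 0, 0, 1,-1,  1,-1, 1,-1,  0, 0, 2,-2,  1,-1, 1,-1, 2,-2, 2,-2};
    const int shell_end[4] = {4, 8, 12, 20};
    if (order < 1) order = 1;
    if (order > 4) order = 4;
    for (int i = 0; i < shell_end[order - 1]; ++i) {
        dx.push_back(sx[i]); dy.push_back(sy[i]);
    }
}

// [[Rcpp::export]]
IntegerMatrix cpm_neighborhood(int order) {
    std::vector<int> dx, dy;
    neigh_offsets(order, dx, dy);
    IntegerMatrix out(dx.size(), 2);
    for (size_t i = 0; i < dx.size(); ++i) { out(i, 0) = dx[i]; out(i, 1) = dy[i]; }
    return out;
}

static inline double J_of(int a, int b, double Jcc, double Jcm) {
    if (a == b) return 0.0;
    if (a > 0 && b > 0) return Jcc;
    return Jcm;
}

// Boundary-energy change at target site (r, c) [0-based] if its index changes
// from `from` to `to`. Sites outside the lattice count as medium.
static double adhesion_delta(const int* sig, int L, int r, int c, int from, int to,
                             double Jcc, double Jcm,
                             const std::vector<int>& dx, const std::vector<int>& dy) {
    double dH = 0.0;
    for (size_t k = 0; k < dx.size(); ++k) {
        int rr = r + dx[k], cc = c + dy[k];
        int nb = (rr >= 0 && rr < L && cc >= 0 && cc < L) ? sig[rr + L * cc] : 0;
        dH += J_of(to, nb, Jcc, Jcm) - J_of(from, nb, Jcc, Jcm);
    }
    return dH;
}

// Area-constraint change when cell `from` loses one site and cell `to` gains one.
static double area_delta(const int* areas, int from, int to,
                         double lambda, double Atarget) {
    double dH = 0.0;
    if (from > 0) {
        double a = areas[from - 1];
        dH += lambda * ((a - 1.0 - Atarget) * (a - 1.0 - Atarget) -
                        (a - Atarget) * (a - Atarget));
    }
    if (to > 0) {
        double a = areas[to - 1];
        dH += lambda * ((a + 1.0 - Atarget) * (a + 1.0 - Atarget) -
                        (a - Atarget) * (a - Atarget));
    }
    return dH;
}

// Full energy change for a copy attempt: source site (sr, sc) copies its index
// into target site (tr, tc); 0-based coordinates.
// [[Rcpp::export]]
double cpm_delta_h_cpp(const IntegerMatrix& sigma, const IntegerVector& areas,
                       const NumericMatrix& sfield, const NumericMatrix& bfield,
                       int tr, int tc, int sr, int sc,
                       double Jcc, double Jcm, double lambda, double Atarget,
                       double mu_b, double mu_s, int order) {
    int L = sigma.nrow();
    std::vector<int> dx, dy;
    neigh_offsets(order, dx, dy);
    int from = sigma(tr, tc);
    int to = sigma(sr, sc);
    if (from == to) return 0.0;
    double dH = adhesion_delta(&sigma[0], L, tr, tc, from, to, Jcc, Jcm, dx, dy);
    dH += area_delta(&areas[0], from, to, lambda, Atarget);
    dH -= mu_b * (bfield(tr, tc) - bfield(sr, sc));
    dH -= mu_s * (sfield(tr, tc) - sfield(sr, sc));
    return dH;
}

// Total energy: each unordered neighbor pair counted once; pairs with virtual
// medium sites beyond the lattice edge are owned by the interior member.
// [[Rcpp::export]]
double cpm_hamiltonian_cpp(const IntegerMatrix& sigma, const IntegerVector& areas,
                           double Jcc, double Jcm, double lambda, double Atarget,
                           int order) {
    int L = sigma.nrow();
    std::vector<int> dx, dy;
    neigh_offsets(order, dx, dy);
    double H = 0.0;
    for (int c = 0; c < L; ++c) {
        for (int r = 0; r < L; ++r) {
            int a = sigma(r, c);
            for (size_t k = 0; k < dx.size(); ++k) {
                int rr = r + dx[k], cc = c + dy[k];
                bool inside = (rr >= 0 && rr < L && cc >= 0 && cc < L);
                if (inside) {
                    // count each interior pair once (lexicographic owner)
                    if (cc > c || (cc == c && rr > r)) {
                        H += J_of(a, sigma(rr, cc), Jcc, Jcm);
                    }
                } else {
                    H += J_of(a, 0, Jcc, Jcm);
                }
            }
        }
    }
    for (int i = 0; i < areas.size(); ++i) {
        double d = areas[i] - Atarget;
        H += lambda * d * d;
    }
    return H;
}

// Yokoi 8-connectivity number of cell `idx` in the Moore ring around
// (r, c): the number of ring components of that cell 4-adjacent to the
// center. 1 means removing the center pixel keeps the cell locally
// connected (simple point); >= 2 means removal would split it; 0 means the
// pixel is isolated within its ring.
static int connectivity_number(const int* sig, int L, int r, int c, int idx) {
    // ring order: E, NE, N, NW, W, SW, S, SE
    const int rr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
    const int cc[8] = {1, 1, 0, -1, -1, -1, 0, 1};
    int x[8];
    for (int k = 0; k < 8; ++k) {
        int r2 = r + rr[k], c2 = c + cc[k];
        x[k] = (r2 >= 0 && r2 < L && c2 >= 0 && c2 < L &&
                sig[r2 + L * c2] == idx) ? 1 : 0;
    }
    int C = 0;
    for (int k = 0; k < 8; k += 2) {
        int xb1 = 1 - x[k];
        int xb2 = 1 - x[(k + 1) % 8];
        int xb3 = 1 - x[(k + 2) % 8];
        C += xb1 - xb1 * xb2 * xb3;
    }
    return C;
}

// Modified Metropolis dynamics. Performs n_mcs sweeps of L*L copy attempts
// each, updating sigma and areas in place (caller passes fresh copies).
// A copy that would annihilate a cell (area 1 -> 0) or split it into
// disconnected pieces (cells are connected subdomains) is rejected
// outright. Uses R's RNG; draw order per attempt: target site, neighbor,
// [uniform].
// [[Rcpp::export]]
List cpm_mcs_cpp(IntegerMatrix sigma, IntegerVector areas,
                 const NumericMatrix& sfield, const NumericMatrix& bfield,
                 int n_mcs,
                 double Jcc, double Jcm, double lambda, double Atarget,
                 double mu_b, double mu_s, double Tfluct,
                 int order, int copy_order) {
    int L = sigma.nrow();
    std::vector<int> dx, dy, cx, cy;
    neigh_offsets(order, dx, dy);
    neigh_offsets(copy_order, cx, cy);
    int ncopy = (int)cx.size();
    int* sig = &sigma[0];
    int* ar = (areas.size() > 0) ? &areas[0] : NULL;
    const double* sf = &sfield[0];
    const double* bf = &bfield[0];
    long long attempts = 0, accepted = 0;
    for (int step = 0; step < n_mcs; ++step) {
        long long n_att = (long long)L * L;
        for (long long i = 0; i < n_att; ++i) {
            ++attempts;
            int tr = (int)(unif_rand() * L); if (tr == L) tr = L - 1;
            int tc = (int)(unif_rand() * L); if (tc == L) tc = L - 1;
            int k = (int)(unif_rand() * ncopy); if (k == ncopy) k = ncopy - 1;
            int sr = tr + cx[k], sc = tc + cy[k];
            if (sr < 0 || sr >= L || sc < 0 || sc >= L) continue;
            int from = sig[tr + L * tc];
            int to = sig[sr + L * sc];
            if (from == to) continue;
            if (from > 0) {
                if (ar[from - 1] == 1) continue;          // no annihilation
                if (connectivity_number(sig, L, tr, tc, from) >= 2)
                    continue;                              // no cell splitting
            }
            double dH = adhesion_delta(sig, L, tr, tc, from, to, Jcc, Jcm, dx, dy);
            dH += area_delta(ar, from, to, lambda, Atarget);
            dH -= mu_b * (bf[tr + L * tc] - bf[sr + L * sc]);
            dH -= mu_s * (sf[tr + L * tc] - sf[sr + L * sc]);
            bool accept;
            if (dH <= 0.0) {
                accept = true;
            } else if (Tfluct <= 0.0) {
                accept = false;
            } else {
                accept = (unif_rand() < std::exp(-dH / Tfluct));
            }
            if (accept) {
                sig[tr + L * tc] = to;
                if (from > 0) --ar[from - 1];
                if (to > 0) ++ar[to - 1];
                ++accepted;
            }
        }
    }
    return List::create(_["attempts"] = (double)attempts,
                        _["accepted"] = (double)accepted);
}
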