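#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One forward-Euler diffusion step with zero-flux (mirror) boundaries,
// writing into `out`. Conserves total mass exactly up to rounding. The
// interior is branch-free; the four edges are handled separately.
static void diffuse_pass(const double* s, double* out, int nr, int nc,
                         double coef) {
    for (int c = 1; c < nc - 1; ++c) {
        const double* col = s + (size_t)nr * c;
        double* oc = out + (size_t)nr * c;
        for (int r = 1; r < nr - 1; ++r) {
            double v = col[r];
            oc[r] = v + coef * (col[r - 1] + col[r + 1] + col[r - nr] +
                                col[r + nr] - 4.0 * v);
        }
    }
    for (int c = 0; c < nc; ++c) {
        for (int r : {0, nr - 1}) {
            size_t i = (size_t)r + (size_t)nr * c;
            double v = s[i];
            double up = (r > 0) ? s[i - 1] : v;
            double dn = (r < nr - 1) ? s[i + 1] : v;
            double lf = (c > 0) ? s[i - nr] : v;
            double rt = (c < nc - 1) ? s[i + nr] : v;
            out[i] = v + coef * (up + dn + lf + rt - 4.0 * v);
        }
    }
    for (int r = 1; r < nr - 1; ++r) {
        for (int c : {0, nc - 1}) {
            size_t i = (size_t)r + (size_t)nr * c;
            double v = s[i];
            double up = s[i - 1], dn = s[i + 1];
            double lf = (c > 0) ? s[i - nr] : v;
            double rt = (c < nc - 1) ? s[i + nr] : v;
            out[i] = v + coef * (up + dn + lf + rt - 4.0 * v);
        }
    }
}

static void diffuse_once(double* s, double* tmp, int nr, int nc, double coef) {
    diffuse_pass(s, tmp, nr, nc, coef);
    std::copy(tmp, tmp + (size_t)nr * nc, s);
}

// [[Rcpp::export]]
NumericMatrix pde_diffuse_cpp(const NumericMatrix& grid, double D, double h2,
                              double dt) {
    NumericMatrix out = clone(grid);
    int nr = out.nrow(), nc = out.ncol();
    std::vector<double> tmp((size_t)nr * nc);
    diffuse_once(&out[0], tmp.data(), nr, nc, D * dt / h2);
    return out;
}

// Operator-split integration of the VEGF/ECM fields over n_sub substeps of
// length dt: mass-action reaction everywhere, then transport of the soluble
// field. mode: 0 = diffusion, 1 = none, 2 = well-mixed (s set to its mean
// after every reaction step). Returns updated copies of the three fields
// plus the number of negative excursions clipped to zero.
// [[Rcpp::export]]
List pde_integrate_cpp(const NumericMatrix& s0, const NumericMatrix& e0,
                       const NumericMatrix& b0, const IntegerMatrix& mask,
                       double alpha_V, double alpha_E, double k_bind,
                       double gamma_s, double D, double h2, double dt,
                       int n_sub, int mode) {
    NumericMatrix s = clone(s0), e = clone(e0), b = clone(b0);
    int nr = s.nrow(), nc = s.ncol();
    size_t n = (size_t)nr * nc;
    double* ps = &s[0];
    double* pe = &e[0];
    double* pb = &b[0];
    const int* pm = &mask[0];
    std::vector<double> buf(n);
    double* cur = ps;            // double-buffer: swap instead of copying
    double* alt = buf.data();
    double coef = D * dt / h2;
    int clipped = 0;
    for (int step = 0; step < n_sub; ++step) {
        for (size_t i = 0; i < n; ++i) {
            double sv = cur[i], ev = pe[i];
            double bind = k_bind * sv * ev;
            double ns = sv + dt * (alpha_V - bind - gamma_s * sv);
            double ne = ev + dt * (alpha_E * (pm[i] > 0 ? 1.0 : 0.0) - bind);
            if (ns < 0.0) { ns = 0.0; ++clipped; }
            if (ne < 0.0) { ne = 0.0; ++clipped; }
            cur[i] = ns; pe[i] = ne; pb[i] += dt * bind;
        }
        if (mode == 0 && D > 0.0) {
            diffuse_pass(cur, alt, nr, nc, coef);
            std::swap(cur, alt);
        } else if (mode == 2) {
            double tot = 0.0;
            for (size_t i = 0; i < n; ++i) tot += cur[i];
            double mean = tot / (double)n;
            for (size_t i = 0; i < n; ++i) cur[i] = mean;
        }
    }
    if (cur != ps) std::copy(cur, cur + n, ps);
    return List::create(_["s"] = s, _["e"] = e, _["b"] = b,
                        _["clipped"] = clipped);
}
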