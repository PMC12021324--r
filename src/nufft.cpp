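#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Modified Bessel function of the first kind, order 0 (power series;
// converges quickly for the kernel-shape arguments used here).
static double bessel_i0(double x) {
    double t = x * x / 4.0, term = 1.0, sum = 1.0;
    for (int k = 1; k < 128; ++k) {
        term *= t / (double(k) * double(k));
        sum += term;
        if (term < 1e-18 * sum) break;
    }
    return sum;
}

// Kaiser-Bessel interpolation kernel with full width J (grid units),
// normalized so kb(0) = 1.
static inline double kb_kernel(double z, double J, double beta, double i0beta) {
    double r = 2.0 * z / J;
    double a = 1.0 - r * r;
    if (a <= 0.0) return 0.0;
    return bessel_i0(beta * std::sqrt(a)) / i0beta;
}

static inline int wrap_index(int i, int N) {
    int r = i % N;
    return r < 0 ? r + N : r;
}

// Gather: evaluate a DC-centered oversampled spectrum at off-grid
// frequency coordinates u, v (grid units in [0, N)). Periodic wrap.
// [[Rcpp::export]]
ComplexVector kb_interp_cpp(const ComplexMatrix& grid,
                            const NumericVector& u, const NumericVector& v,
                            int J, double beta) {
    const int N = grid.nrow();
    const int M = u.size();
    const double i0beta = bessel_i0(beta);
    const int half = J / 2;
    ComplexVector out(M);
    std::vector<double> wx(J + 1), wy(J + 1);
    for (int j = 0; j < M; ++j) {
        const double gu = u[j], gv = v[j];
        const int iu0 = (int)std::ceil(gu - half);
        const int iv0 = (int)std::ceil(gv - half);
        int nu = 0, nv = 0;
        for (int p = iu0; p <= (int)std::floor(gu + half); ++p)
            wx[nu++] = kb_kernel(gu - p, (double)J, beta, i0beta);
        for (int q = iv0; q <= (int)std::floor(gv + half); ++q)
            wy[nv++] = kb_kernel(gv - q, (double)J, beta, i0beta);
        double accr = 0.0, acci = 0.0;
        for (int a = 0; a < nu; ++a) {
            const int iu = wrap_index(iu0 + a, N);
            for (int b = 0; b < nv; ++b) {
                const int iv = wrap_index(iv0 + b, N);
                const Rcomplex g = grid(iu, iv);
                const double w = wx[a] * wy[b];
                accr += w * g.r;
                acci += w * g.i;
            }
        }
        out[j].r = accr;
        out[j].i = acci;
    }
    return out;
}

// Scatter: exact adjoint of kb_interp_cpp (same kernel weights).
// [[Rcpp::export]]
ComplexMatrix kb_spread_cpp(const ComplexVector& vals,
                            const NumericVector& u, const NumericVector& v,
                            int N, int J, double beta) {
    const int M = vals.size();
    const double i0beta = bessel_i0(beta);
    const int half = J / 2;
    ComplexMatrix grid(N, N);
    std::vector<double> wx(J + 1), wy(J + 1);
    for (int j = 0; j < M; ++j) {
        const double gu = u[j], gv = v[j];
        const int iu0 = (int)std::ceil(gu - half);
        const int iv0 = (int)std::ceil(gv - half);
        int nu = 0, nv = 0;
        for (int p = iu0; p <= (int)std::floor(gu + half); ++p)
            wx[nu++] = kb_kernel(gu - p, (double)J, beta, i0beta);
        for (int q = iv0; q <= (int)std::floor(gv + half); ++q)
            wy[nv++] = kb_kernel(gv - q, (double)J, beta, i0beta);
        const double vr = vals[j].r, vi = vals[j].i;
        for (int a = 0; a < nu; ++a) {
            const int iu = wrap_index(iu0 + a, N);
            for (int b = 0; b < nv; ++b) {
                const int iv = wrap_index(iv0 + b, N);
                const double w = wx[a] * wy[b];
                grid(iu, iv).r += w * vr;
                grid(iu, iv).i += w * vi;
            }
        }
    }
    return grid;
}

// Direct type-2 non-uniform DFT: F[j] = sum_x d[x] exp(-i (wx[j]*x + wy[j]*y))
// with pixel offsets centered at floor(n/2). Exact oracle for small grids.
// [[Rcpp::export]]
ComplexVector nudft2_forward_cpp(const ComplexMatrix& img,
                                 const NumericVector& wx,
                                 const NumericVector& wy) {
    const int n1 = img.nrow(), n2 = img.ncol();
    const int c1 = n1 / 2, c2 = n2 / 2;
    const int M = wx.size();
    ComplexVector out(M);
    for (int j = 0; j < M; ++j) {
        double accr = 0.0, acci = 0.0;
        for (int q = 0; q < n2; ++q) {
            const double py = wy[j] * (q - c2);
            for (int p = 0; p < n1; ++p) {
                const double ph = wx[j] * (p - c1) + py;
                const double cs = std::cos(ph), sn = std::sin(ph);
                const Rcomplex d = img(p, q);
                // exp(-i ph) = cs - i sn
                accr += d.r * cs + d.i * sn;
                acci += -d.r * sn + d.i * cs;
            }
        }
        out[j].r = accr;
        out[j].i = acci;
    }
    return out;
}

// Direct adjoint of nudft2_forward_cpp.
// [[Rcpp::export]]
ComplexMatrix nudft2_adjoint_cpp(const ComplexVector& vals,
                                 const NumericVector& wx,
                                 const NumericVector& wy,
                                 int n1, int n2) {
    const int c1 = n1 / 2, c2 = n2 / 2;
    const int M = vals.size();
    ComplexMatrix img(n1, n2);
    for (int j = 0; j < M; ++j) {
        const double vr = vals[j].r, vi = vals[j].i;
        for (int q = 0; q < n2; ++q) {
            const double py = wy[j] * (q - c2);
            for (int p = 0; p < n1; ++p) {
                const double ph = wx[j] * (p - c1) + py;
                const double cs = std::cos(ph), sn = std::sin(ph);
                // exp(+i ph) * v
                img(p, q).r += vr * cs - vi * sn;
                img(p, q).i += vr * sn + vi * cs;
            }
        }
    }
    return img;
}
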