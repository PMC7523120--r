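// Fused kernels for the additive monotonic decoder.
//
// The AMNN evaluates p one-input integrand networks (one hidden tanh layer,
// exponential output) on every point of a per-dimension quadrature grid:
//   hint[i, c] = exp( sum_k W2[k,j] * tanh(M[i,c] * W1[k,j] + B1[k,j]) + B2[j] )
// where column c belongs to latent dimension j. Doing this with generic
// matrix ops allocates many n x (p*grid*h) intermediates; these kernels fuse
// the loops and store only the hidden activations needed for the backward
// pass (layout: hidden unit fastest, so reads and writes are contiguous).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// overflow guard on the integrand's exponent
static const double EXP_CLAMP = 60.0;

// [[Rcpp::export]]
List amnn_kernel_fwd(const NumericMatrix& M, const NumericMatrix& W1,
                     const NumericMatrix& B1, const NumericMatrix& W2,
                     const NumericVector& B2, const int G1) {
  const int n = M.nrow(), ncol = M.ncol(), h = W1.nrow();
  const int p = W1.ncol();
  if (ncol != p * G1) stop("grid/dimension mismatch");
  NumericMatrix hint(n, ncol);
  NumericVector act(static_cast<R_xlen_t>(n) * ncol * h);
  const double* Mp = M.begin();
  double* hp = hint.begin();
  double* ap = act.begin();
  for (int c = 0; c < ncol; ++c) {
    const int j = c / G1;
    const double* w1 = &W1(0, j);
    const double* b1 = &B1(0, j);
    const double* w2 = &W2(0, j);
    const double b2 = B2[j];
    const double* mc = Mp + static_cast<R_xlen_t>(c) * n;
    double* hc = hp + static_cast<R_xlen_t>(c) * n;
    double* ac = ap + static_cast<R_xlen_t>(c) * n * h;
    for (int i = 0; i < n; ++i) {
      const double m = mc[i];
      double s = b2;
      double* ai = ac + static_cast<R_xlen_t>(i) * h;
      for (int k = 0; k < h; ++k) {
        const double a = std::tanh(m * w1[k] + b1[k]);
        ai[k] = a;
        s += w2[k] * a;
      }
      hc[i] = std::exp(s > EXP_CLAMP ? EXP_CLAMP : s);
    }
  }
  return List::create(_["hint"] = hint, _["act"] = act);
}

// [[Rcpp::export]]
List amnn_kernel_bwd(const NumericMatrix& Gr, const NumericMatrix& hint,
                     const NumericVector& act, const NumericMatrix& M,
                     const NumericMatrix& W1, const NumericMatrix& W2,
                     const int G1) {
  const int n = M.nrow(), ncol = M.ncol(), h = W1.nrow();
  const int p = W1.ncol();
  NumericMatrix gM(n, ncol);
  NumericMatrix gW1(h, p), gB1(h, p), gW2(h, p);
  NumericVector gB2(p);
  const double* ap = act.begin();
  const double lim = std::exp(EXP_CLAMP) * 0.999999;  // clamp region: no grad
  for (int c = 0; c < ncol; ++c) {
    const int j = c / G1;
    const double* w1 = &W1(0, j);
    const double* w2 = &W2(0, j);
    double* gw1 = &gW1(0, j);
    double* gb1 = &gB1(0, j);
    double* gw2 = &gW2(0, j);
    const double* ac = ap + static_cast<R_xlen_t>(c) * n * h;
    for (int i = 0; i < n; ++i) {
      const double y = hint(i, c);
      double gy = Gr(i, c) * y;
      if (y >= lim) gy = 0.0;
      if (gy == 0.0) continue;
      gB2[j] += gy;
      double gm = 0.0;
      const double m = M(i, c);
      const double* ai = ac + static_cast<R_xlen_t>(i) * h;
      for (int k = 0; k < h; ++k) {
        const double a = ai[k];
        const double u = gy * w2[k] * (1.0 - a * a);
        gw2[k] += gy * a;
        gw1[k] += u * m;
        gb1[k] += u;
        gm += u * w1[k];
      }
      gM(i, c) = gm;
    }
  }
  return List::create(_["gM"] = gM, _["gW1"] = gW1, _["gB1"] = gB1,
                      _["gW2"] = gW2, _["gB2"] = gB2);
}
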