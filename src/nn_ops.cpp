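#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fused Adam update, in place on parameter/state buffers the caller owns.
// bc1/bc2 are the bias-correction factors 1 - beta^t.
// [[Rcpp::export]]
void adam_update_inplace(NumericVector p, NumericVector g,
                         NumericVector m, NumericVector v,
                         double lr, double b1, double b2, double eps,
                         double bc1, double bc2) {
  R_xlen_t n = p.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i];
    double mi = b1 * m[i] + (1.0 - b1) * gi;
    double vi = b2 * v[i] + (1.0 - b2) * gi * gi;
    m[i] = mi;
    v[i] = vi;
    p[i] -= lr * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
  }
}

// Zero-padded "same" im2col over sample-major rows (row b*L + l holds
// sample b, timestep l). Output column block j holds the input shifted by
// j - (k-1)/2 timesteps within each sample.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericMatrix x2, int B, int L, int k) {
  int C = x2.ncol();
  int pad = (k - 1) / 2;
  int n = B * L;
  NumericMatrix M(n, k * C);
  for (int j = 0; j < k; ++j) {
    int o = j - pad;
    for (int c = 0; c < C; ++c) {
      const double* src = &x2(0, c);
      double* dst = &M(0, j * C + c);
      for (int b = 0; b < B; ++b) {
        const double* sb = src + (R_xlen_t)b * L;
        double* db = dst + (R_xlen_t)b * L;
        for (int l = 0; l < L; ++l) {
          int li = l + o;
          db[l] = (li >= 0 && li < L) ? sb[li] : 0.0;
        }
      }
    }
  }
  return M;
}

// Scatter the im2col gradient back onto the input rows (adjoint of
// im2col_cpp).
// [[Rcpp::export]]
NumericMatrix col2im_cpp(NumericMatrix dM, int B, int L, int k, int C) {
  int n = B * L;
  NumericMatrix dx(n, C);
  int pad = (k - 1) / 2;
  for (int j = 0; j < k; ++j) {
    int o = j - pad;
    for (int c = 0; c < C; ++c) {
      const double* src = &dM(0, j * C + c);
      double* dst = &dx(0, c);
      for (int b = 0; b < B; ++b) {
        const double* sb = src + (R_xlen_t)b * L;
        double* db = dst + (R_xlen_t)b * L;
        for (int l = 0; l < L; ++l) {
          int li = l + o;
          if (li >= 0 && li < L) db[li] += sb[l];
        }
      }
    }
  }
  return dx;
}

// Sample-major (B*L, F) -> per-sample flat (B, L*F); column f*L + l.
// [[Rcpp::export]]
NumericMatrix flatten_cpp(NumericMatrix h, int B, int L) {
  int F = h.ncol();
  NumericMatrix out(B, L * F);
  for (int f = 0; f < F; ++f) {
    const double* src = &h(0, f);
    for (int b = 0; b < B; ++b) {
      const double* sb = src + (R_xlen_t)b * L;
      for (int l = 0; l < L; ++l) {
        out(b, f * L + l) = sb[l];
      }
    }
  }
  return out;
}

// Inverse of flatten_cpp.
// [[Rcpp::export]]
NumericMatrix unflatten_cpp(NumericMatrix hf, int B, int L) {
  int F = hf.ncol() / L;
  NumericMatrix out((R_xlen_t)B * L, F);
  for (int f = 0; f < F; ++f) {
    double* dst = &out(0, f);
    for (int b = 0; b < B; ++b) {
      double* db = dst + (R_xlen_t)b * L;
      for (int l = 0; l < L; ++l) {
        db[l] = hf(b, f * L + l);
      }
    }
  }
  return out;
}
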