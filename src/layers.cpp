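#include <Rcpp.h>
using namespace Rcpp;

// Hot inner loops of the 1D convolution / max-pooling layers.
// Activations are C x (n*L) matrices, channel-major, with column index
// (sample-1)*L + position.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& B, const IntegerVector& cols,
                         int k, int dilation) {
  const int Cin = B.nrow();
  const int nw = cols.size();
  NumericMatrix X(k * Cin, nw);
  const double* pb = REAL(B);
  double* px = REAL(X);
  for (int w = 0; w < nw; ++w) {
    double* dst = px + (size_t)w * k * Cin;
    for (int j = 0; j < k; ++j) {
      const double* srcc = pb + (size_t)(cols[w] - 1 + j * dilation) * Cin;
      std::copy(srcc, srcc + Cin, dst + (size_t)j * Cin);
    }
  }
  return X;
}

// [[Rcpp::export]]
NumericMatrix cpp_conv_bwd_scatter(const NumericMatrix& dXcol,
                                   const IntegerVector& cols, int Cin,
                                   int k, int dilation, int nColsB) {
  const int nw = cols.size();
  NumericMatrix dB(Cin, nColsB);
  const double* ps = REAL(dXcol);
  double* pd = REAL(dB);
  for (int w = 0; w < nw; ++w) {
    const double* src = ps + (size_t)w * k * Cin;
    for (int j = 0; j < k; ++j) {
      double* dst = pd + (size_t)(cols[w] - 1 + j * dilation) * Cin;
      const double* s = src + (size_t)j * Cin;
      for (int c = 0; c < Cin; ++c) dst[c] += s[c];
    }
  }
  return dB;
}

// [[Rcpp::export]]
List cpp_pool_fwd(const NumericMatrix& Z, int n, int L, int p) {
  const int C = Z.nrow();
  const int L2 = L / p;
  NumericMatrix M(C, n * L2);
  IntegerMatrix J(C, n * L2);
  const double* pz = REAL(Z);
  double* pm = REAL(M);
  int* pj = INTEGER(J);
  for (int i = 0; i < n; ++i) {
    for (int l = 0; l < L2; ++l) {
      const size_t out = ((size_t)i * L2 + l) * C;
      const size_t in0 = ((size_t)i * L + (size_t)l * p) * C;
      for (int c = 0; c < C; ++c) {
        double best = pz[in0 + c];
        int arg = 1;
        for (int j = 1; j < p; ++j) {
          double v = pz[in0 + (size_t)j * C + c];
          if (v > best) { best = v; arg = j + 1; }
        }
        pm[out + c] = best;
        pj[out + c] = arg;
      }
    }
  }
  return List::create(_["M"] = M, _["J"] = J, _["L2"] = L2);
}

// [[Rcpp::export]]
NumericMatrix cpp_pool_bwd(const NumericMatrix& dM, const IntegerMatrix& J,
                           int n, int L, int p) {
  const int C = dM.nrow();
  const int L2 = L / p;
  NumericMatrix dZ(C, n * L);
  const double* ps = REAL(dM);
  const int* pj = INTEGER(J);
  double* pd = REAL(dZ);
  for (int i = 0; i < n; ++i) {
    for (int l = 0; l < L2; ++l) {
      const size_t in = ((size_t)i * L2 + l) * C;
      const size_t out0 = ((size_t)i * L + (size_t)l * p) * C;
      for (int c = 0; c < C; ++c)
        pd[out0 + (size_t)(pj[in + c] - 1) * C + c] = ps[in + c];
    }
  }
  return dZ;
}
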