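#include <Rcpp.h>
using namespace Rcpp;

// Layout helpers for [H, W, C, N] image arrays. "mat" layout is
// (H*W*N) x C with spatial position fastest, then sample.

// [[Rcpp::export(name = ".img_to_mat")]]
NumericMatrix img_to_mat(NumericVector X) {
  IntegerVector d = X.attr("dim");
  int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericMatrix out(HW * N, C);
  const double* x = X.begin();
  for (int c = 0; c < C; ++c) {
    double* o = &out(0, c);
    for (int n = 0; n < N; ++n) {
      const double* src = x + (size_t)HW * (c + (size_t)C * n);
      std::copy(src, src + HW, o + (size_t)HW * n);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".mat_to_img")]]
NumericVector mat_to_img(NumericMatrix M, int H, int W, int C, int N) {
  int HW = H * W;
  NumericVector out((size_t)HW * C * N);
  double* o = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* m = &M(0, c);
    for (int n = 0; n < N; ++n) {
      const double* src = m + (size_t)HW * n;
      std::copy(src, src + HW, o + (size_t)HW * (c + (size_t)C * n));
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

// Gather patches: Xm is (S x N) flattened padded volume per sample, idx is
// (P x Q) 1-based indices into the volume. Output (P*N) x Q.
// [[Rcpp::export(name = ".im2col_cpp")]]
NumericMatrix im2col_cpp(NumericMatrix Xm, IntegerMatrix idx, int N) {
  int P = idx.nrow(), Q = idx.ncol();
  NumericMatrix out(P * N, Q);
  for (int q = 0; q < Q; ++q) {
    const int* id = &idx(0, q);
    double* o = &out(0, q);
    for (int n = 0; n < N; ++n) {
      const double* x = &Xm(0, n);
      double* on = o + (size_t)P * n;
      for (int p = 0; p < P; ++p) on[p] = x[id[p] - 1];
    }
  }
  return out;
}

// Scatter-add transpose of im2col: accumulate patch values back into the
// padded volume. cols is (P*N) x Q; output S x N.
// [[Rcpp::export(name = ".col2im_cpp")]]
NumericMatrix col2im_cpp(NumericMatrix cols, IntegerMatrix idx, int S, int N) {
  int P = idx.nrow(), Q = idx.ncol();
  NumericMatrix out(S, N);
  for (int q = 0; q < Q; ++q) {
    const int* id = &idx(0, q);
    const double* c = &cols(0, q);
    for (int n = 0; n < N; ++n) {
      double* o = &out(0, n);
      const double* cn = c + (size_t)P * n;
      for (int p = 0; p < P; ++p) o[id[p] - 1] += cn[p];
    }
  }
  return out;
}

// out[i,j] = M[i,j] * scale[j] + shift[j]
// [[Rcpp::export(name = ".col_affine")]]
NumericMatrix col_affine(NumericMatrix M, NumericVector scale,
                         NumericVector shift) {
  int m = M.nrow(), C = M.ncol();
  NumericMatrix out(m, C);
  for (int j = 0; j < C; ++j) {
    const double* x = &M(0, j);
    double* o = &out(0, j);
    double s = scale[j], t = shift[j];
    for (int i = 0; i < m; ++i) o[i] = x[i] * s + t;
  }
  return out;
}

// Fused batch-norm input gradient:
// out[i,j] = ((dxhat[i,j] - c1[j]) - xhat[i,j] * c2[j]) * ivar[j]
// [[Rcpp::export(name = ".bn_bwd_core")]]
NumericMatrix bn_bwd_core(NumericMatrix dxhat, NumericMatrix xhat,
                          NumericVector c1, NumericVector c2,
                          NumericVector ivar) {
  int m = dxhat.nrow(), C = dxhat.ncol();
  NumericMatrix out(m, C);
  for (int j = 0; j < C; ++j) {
    const double* dx = &dxhat(0, j);
    const double* xh = &xhat(0, j);
    double* o = &out(0, j);
    double a = c1[j], b = c2[j], v = ivar[j];
    for (int i = 0; i < m; ++i) o[i] = ((dx[i] - a) - xh[i] * b) * v;
  }
  return out;
}
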