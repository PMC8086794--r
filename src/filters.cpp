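#include <Rcpp.h>
using namespace Rcpp;

// reflect index into [0, n): half-sample symmetric (x[-1] -> x[0])
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// Separable convolution with reflected borders. kr is applied along rows
// (vertical, within a column), kc along columns (horizontal). Kernels are
// centered (odd length).
// [[Rcpp::export]]
NumericMatrix sep_convolve_cpp(const NumericMatrix& img,
                               const NumericVector& kr,
                               const NumericVector& kc) {
  const int h = img.nrow(), w = img.ncol();
  const int nr = kr.size(), nc = kc.size();
  const int rr = nr / 2, rc = nc / 2;
  NumericMatrix tmp(h, w), out(h, w);

  const double* kr_p = &kr[0];
  const double* kc_p = &kc[0];

  // vertical pass: contiguous within a column; reflect only near borders
  for (int j = 0; j < w; ++j) {
    const double* col = &img(0, j);
    double* dst = &tmp(0, j);
    int lo = std::min(rr, h), hi = std::max(lo, h - rr);
    for (int i = 0; i < lo; ++i) {
      double acc = 0.0;
      for (int k = 0; k < nr; ++k)
        acc += kr_p[k] * col[reflect_idx(i + k - rr, h)];
      dst[i] = acc;
    }
    for (int i = lo; i < hi; ++i) {
      double acc = 0.0;
      const double* src = col + i - rr;
      for (int k = 0; k < nr; ++k) acc += kr_p[k] * src[k];
      dst[i] = acc;
    }
    for (int i = hi; i < h; ++i) {
      double acc = 0.0;
      for (int k = 0; k < nr; ++k)
        acc += kr_p[k] * col[reflect_idx(i + k - rr, h)];
      dst[i] = acc;
    }
  }
  // horizontal pass: accumulate whole columns at a time
  std::fill(out.begin(), out.end(), 0.0);
  for (int j = 0; j < w; ++j) {
    double* dst = &out(0, j);
    for (int k = 0; k < nc; ++k) {
      const double* src = &tmp(0, reflect_idx(j + k - rc, w));
      const double kk = kc_p[k];
      for (int i = 0; i < h; ++i) dst[i] += kk * src[i];
    }
  }
  return out;
}
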