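#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// One iteration of binary erosion with a 3x3 square structuring element;
// pixels outside the frame count as background.
static void erode_once(const std::vector<char>& in, std::vector<char>& out,
                       int h, int w) {
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      char v = 1;
      for (int dj = -1; dj <= 1 && v; ++dj) {
        for (int di = -1; di <= 1 && v; ++di) {
          int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= h || jj < 0 || jj >= w || !in[ii + (size_t)jj * h])
            v = 0;
        }
      }
      out[i + (size_t)j * h] = v;
    }
  }
}

// [[Rcpp::export]]
LogicalMatrix erode_cpp(const LogicalMatrix& mask, int count) {
  const int h = mask.nrow(), w = mask.ncol();
  std::vector<char> a((size_t)h * w), b((size_t)h * w);
  for (size_t k = 0; k < a.size(); ++k) a[k] = mask[k] ? 1 : 0;
  for (int it = 0; it < count; ++it) { erode_once(a, b, h, w); a.swap(b); }
  LogicalMatrix out(h, w);
  for (size_t k = 0; k < a.size(); ++k) out[k] = a[k] != 0;
  return out;
}

// [[Rcpp::export]]
LogicalMatrix dilate_cpp(const LogicalMatrix& mask, int count) {
  const int h = mask.nrow(), w = mask.ncol();
  // dilation = complement of erosion of the complement
  std::vector<char> a((size_t)h * w), b((size_t)h * w);
  for (size_t k = 0; k < a.size(); ++k) a[k] = mask[k] ? 0 : 1;
  for (int it = 0; it < count; ++it) { erode_once(a, b, h, w); a.swap(b); }
  LogicalMatrix out(h, w);
  for (size_t k = 0; k < a.size(); ++k) out[k] = a[k] == 0;
  return out;
}

// Fill holes: background components (4-connectivity) not connected to the
// frame border become foreground.
// [[Rcpp::export]]
LogicalMatrix fill_holes_cpp(const LogicalMatrix& mask) {
  const int h = mask.nrow(), w = mask.ncol();
  std::vector<char> reach((size_t)h * w, 0);
  std::queue<int> q;
  auto push = [&](int i, int j) {
    size_t k = i + (size_t)j * h;
    if (!mask[k] && !reach[k]) { reach[k] = 1; q.push((int)k); }
  };
  for (int j = 0; j < w; ++j) { push(0, j); push(h - 1, j); }
  for (int i = 0; i < h; ++i) { push(i, 0); push(i, w - 1); }
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int k = q.front(); q.pop();
    int i = k % h, j = k / h;
    for (int d = 0; d < 4; ++d) {
      int ii = i + di[d], jj = j + dj[d];
      if (ii >= 0 && ii < h && jj >= 0 && jj < w) push(ii, jj);
    }
  }
  LogicalMatrix out(h, w);
  for (size_t k = 0; k < (size_t)h * w; ++k) out[k] = mask[k] || !reach[k];
  return out;
}

// Connected-component labeling (connectivity 4 or 8); 0 = background.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::fill(lab.begin(), lab.end(), 0);
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nd = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<int> q;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      size_t k = i + (size_t)j * h;
      if (!mask[k] || lab[k]) continue;
      lab[k] = ++next;
      q.push((int)k);
      while (!q.empty()) {
        int kk = q.front(); q.pop();
        int ci = kk % h, cj = kk / h;
        for (int d = 0; d < nd; ++d) {
          int ii = ci + di8[d], jj = cj + dj8[d];
          if (ii < 0 || ii >= h || jj < 0 || jj >= w) continue;
          size_t kn = ii + (size_t)jj * h;
          if (mask[kn] && !lab[kn]) { lab[kn] = next; q.push((int)kn); }
        }
      }
    }
  }
  return lab;
}

// Iterated conditional modes for the 2-class Potts model.
// cost_obj/cost_bg are unary costs; lambda the pairwise weight (4-neighbors).
// init: true = object. Raster sweeps until no change or max_sweeps.
// Ties go to background.
// [[Rcpp::export]]
LogicalMatrix icm_potts_cpp(const NumericMatrix& cost_obj,
                            const NumericMatrix& cost_bg,
                            double lambda, const LogicalMatrix& init,
                            int max_sweeps) {
  const int h = cost_obj.nrow(), w = cost_obj.ncol();
  std::vector<char> lab((size_t)h * w);
  for (size_t k = 0; k < lab.size(); ++k) lab[k] = init[k] ? 1 : 0;
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool changed = false;
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        size_t k = i + (size_t)j * h;
        int n_obj = 0, n_bg = 0;
        for (int d = 0; d < 4; ++d) {
          int ii = i + di[d], jj = j + dj[d];
          if (ii < 0 || ii >= h || jj < 0 || jj >= w) continue;
          if (lab[ii + (size_t)jj * h]) ++n_obj; else ++n_bg;
        }
        double e_obj = cost_obj(i, j) + lambda * n_bg;
        double e_bg  = cost_bg(i, j) + lambda * n_obj;
        char want = (e_obj < e_bg) ? 1 : 0;  // ties -> background
        if (want != lab[k]) { lab[k] = want; changed = true; }
      }
    }
    if (!changed) break;
  }
  LogicalMatrix out(h, w);
  for (size_t k = 0; k < lab.size(); ++k) out[k] = lab[k] != 0;
  return out;
}
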