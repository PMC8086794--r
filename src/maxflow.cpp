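#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Dinic max-flow on an explicit arc list; used for exact 2-class Potts
// minimization (s-t min cut) in regularize().
namespace {

struct Dinic {
  int n;
  std::vector<int> to, nxt, head;
  std::vector<double> cap;
  std::vector<int> level, iter;

  explicit Dinic(int n_) : n(n_), head(n_, -1), level(n_), iter(n_) {}

  void add_edge(int u, int v, double c_uv, double c_vu) {
    to.push_back(v); cap.push_back(c_uv); nxt.push_back(head[u]);
    head[u] = (int)to.size() - 1;
    to.push_back(u); cap.push_back(c_vu); nxt.push_back(head[v]);
    head[v] = (int)to.size() - 1;
  }

  bool bfs(int s, int t) {
    std::fill(level.begin(), level.end(), -1);
    std::queue<int> q;
    level[s] = 0; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int e = head[u]; e != -1; e = nxt[e]) {
        if (cap[e] > 1e-12 && level[to[e]] < 0) {
          level[to[e]] = level[u] + 1;
          q.push(to[e]);
        }
      }
    }
    return level[t] >= 0;
  }

  double dfs(int u, int t, double f) {
    if (u == t) return f;
    for (int& e = iter[u]; e != -1; e = nxt[e]) {
      int v = to[e];
      if (cap[e] > 1e-12 && level[v] == level[u] + 1) {
        double d = dfs(v, t, std::min(f, cap[e]));
        if (d > 0) { cap[e] -= d; cap[e ^ 1] += d; return d; }
      }
    }
    return 0.0;
  }

  void run(int s, int t) {
    while (bfs(s, t)) {
      for (int i = 0; i < n; ++i) iter[i] = head[i];
      while (dfs(s, t, std::numeric_limits<double>::infinity()) > 0) {}
    }
  }

  // nodes reachable from s in the residual graph
  std::vector<char> source_side(int s) {
    std::vector<char> vis(n, 0);
    std::queue<int> q;
    vis[s] = 1; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int e = head[u]; e != -1; e = nxt[e]) {
        if (cap[e] > 1e-12 && !vis[to[e]]) { vis[to[e]] = 1; q.push(to[e]); }
      }
    }
    return vis;
  }
};

}  // namespace

// Exact minimizer of
//   E(L) = sum_p cost_obj(p)[L_p=obj] + cost_bg(p)[L_p=bg]
//          + lambda * sum_{4-neighbors} [L_p != L_q]
// Returns the object mask (TRUE = object). A tiny bias on the object cost
// resolves ties toward background.
// [[Rcpp::export]]
LogicalMatrix graphcut_potts_cpp(const NumericMatrix& cost_obj,
                                 const NumericMatrix& cost_bg,
                                 double lambda) {
  const int h = cost_obj.nrow(), w = cost_obj.ncol();
  const int n = h * w, s = n, t = n + 1;
  Dinic g(n + 2);
  const double eps = 1e-9;  // tie-break: background wins equal energy
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      int p = i + j * h;
      g.add_edge(s, p, cost_bg(i, j), 0.0);          // cut if p background
      g.add_edge(p, t, cost_obj(i, j) + eps, 0.0);   // cut if p object
    }
  }
  if (lambda > 0) {
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        int p = i + j * h;
        if (i + 1 < h) g.add_edge(p, p + 1, lambda, lambda);
        if (j + 1 < w) g.add_edge(p, p + h, lambda, lambda);
      }
    }
  }
  g.run(s, t);
  std::vector<char> vis = g.source_side(s);
  LogicalMatrix out(h, w);
  for (int p = 0; p < n; ++p) out[p] = vis[p] != 0;  // source side = object
  return out;
}
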