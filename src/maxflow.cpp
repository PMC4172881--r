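#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Dinic max-flow / min-cut on a directed graph with real capacities.
// Arc storage: forward-star with paired reverse arcs (i ^ 1).

namespace {

struct Arc { int to; double cap; int next; };

struct Dinic {
  std::vector<Arc> arcs;
  std::vector<int> head, level, ptr;
  int n;
  static constexpr double EPS = 1e-11;

  explicit Dinic(int n_) : head(n_, -1), level(n_), ptr(n_), n(n_) {}

  void add_arc(int u, int v, double c) {
    arcs.push_back({v, c, head[u]}); head[u] = (int)arcs.size() - 1;
    arcs.push_back({u, 0.0, head[v]}); head[v] = (int)arcs.size() - 1;
  }

  bool bfs(int s, int t) {
    std::fill(level.begin(), level.end(), -1);
    std::queue<int> q;
    level[s] = 0; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int i = head[u]; i != -1; i = arcs[i].next) {
        if (arcs[i].cap > EPS && level[arcs[i].to] < 0) {
          level[arcs[i].to] = level[u] + 1;
          q.push(arcs[i].to);
        }
      }
    }
    return level[t] >= 0;
  }

  double dfs(int u, int t, double pushed) {
    if (u == t) return pushed;
    for (int& i = ptr[u]; i != -1; i = arcs[i].next) {
      int v = arcs[i].to;
      if (arcs[i].cap > EPS && level[v] == level[u] + 1) {
        double got = dfs(v, t, std::min(pushed, arcs[i].cap));
        if (got > EPS) {
          arcs[i].cap -= got;
          arcs[i ^ 1].cap += got;
          return got;
        }
      }
    }
    level[u] = -1;  // dead end
    return 0.0;
  }

  double run(int s, int t) {
    double flow = 0.0;
    while (bfs(s, t)) {
      for (int u = 0; u < n; ++u) ptr[u] = head[u];
      while (true) {
        double got = dfs(s, t, std::numeric_limits<double>::infinity());
        if (got <= EPS) break;
        flow += got;
      }
    }
    return flow;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_mincut(int n, const IntegerVector& from, const IntegerVector& to,
                const NumericVector& cap, int src, int snk) {
  Dinic d(n);
  const int m = from.size();
  d.arcs.reserve(2 * (size_t)m);
  for (int i = 0; i < m; ++i)
    if (cap[i] > 0) d.add_arc(from[i], to[i], cap[i]);
  double flow = d.run(src, snk);
  // source side of the min cut: residual reachability from src
  LogicalVector side(n, false);
  std::vector<char> seen(n, 0);
  std::queue<int> q; q.push(src); seen[src] = 1;
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (int i = d.head[u]; i != -1; i = d.arcs[i].next) {
      int v = d.arcs[i].to;
      if (d.arcs[i].cap > Dinic::EPS && !seen[v]) { seen[v] = 1; q.push(v); }
    }
  }
  for (int u = 0; u < n; ++u) side[u] = seen[u] != 0;
  return List::create(_["flow"] = flow, _["source_side"] = side);
}
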