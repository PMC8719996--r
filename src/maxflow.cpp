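#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>

using namespace Rcpp;

// Dinic's max-flow on a directed graph with real-valued capacities.
// Nodes are 1-based on the R side.  Returns the flow value and the
// source-side node set of a minimum cut (reachability in the residual
// graph), which by the max-flow/min-cut theorem has crossing capacity
// equal to the flow value.

namespace {

struct Arc {
  int to;
  double cap;
  int rev;  // index of the reverse arc in graph[to]
};

class Dinic {
 public:
  explicit Dinic(int n) : g_(n), level_(n), iter_(n) {}

  void add_edge(int from, int to, double cap) {
    g_[from].push_back({to, cap, static_cast<int>(g_[to].size())});
    g_[to].push_back({from, 0.0, static_cast<int>(g_[from].size()) - 1});
  }

  bool bfs(int s, int t) {
    std::fill(level_.begin(), level_.end(), -1);
    std::queue<int> q;
    level_[s] = 0;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (const Arc& a : g_[v]) {
        if (a.cap > EPS && level_[a.to] < 0) {
          level_[a.to] = level_[v] + 1;
          q.push(a.to);
        }
      }
    }
    return level_[t] >= 0;
  }

  double dfs(int v, int t, double f) {
    if (v == t) return f;
    for (int& i = iter_[v]; i < static_cast<int>(g_[v].size()); ++i) {
      Arc& a = g_[v][i];
      if (a.cap > EPS && level_[v] < level_[a.to]) {
        double d = dfs(a.to, t, std::min(f, a.cap));
        if (d > EPS) {
          a.cap -= d;
          g_[a.to][a.rev].cap += d;
          return d;
        }
      }
    }
    return 0.0;
  }

  double run(int s, int t) {
    double flow = 0.0;
    while (bfs(s, t)) {
      std::fill(iter_.begin(), iter_.end(), 0);
      double f;
      while ((f = dfs(s, t, std::numeric_limits<double>::infinity())) > EPS)
        flow += f;
    }
    return flow;
  }

  // source-side of the min cut: residual reachability from s
  std::vector<int> source_side(int s) {
    std::vector<char> seen(g_.size(), 0);
    std::queue<int> q;
    seen[s] = 1;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (const Arc& a : g_[v]) {
        if (a.cap > EPS && !seen[a.to]) {
          seen[a.to] = 1;
          q.push(a.to);
        }
      }
    }
    std::vector<int> out;
    for (int v = 0; v < static_cast<int>(g_.size()); ++v)
      if (seen[v]) out.push_back(v + 1);  // back to 1-based
    return out;
  }

  static constexpr double EPS = 1e-12;

 private:
  std::vector<std::vector<Arc>> g_;
  std::vector<int> level_;
  std::vector<int> iter_;
};

}  // namespace

// [[Rcpp::export]]
List maxflow_dinic(int n_nodes, IntegerVector from, IntegerVector to,
                   NumericVector cap, int source, int sink) {
  if (from.size() != to.size() || from.size() != cap.size())
    stop("edge vectors must have equal length");
  Dinic d(n_nodes);
  for (R_xlen_t i = 0; i < from.size(); ++i) {
    if (cap[i] < 0) stop("negative capacity");
    d.add_edge(from[i] - 1, to[i] - 1, cap[i]);
  }
  double flow = d.run(source - 1, sink - 1);
  std::vector<int> side = d.source_side(source - 1);
  return List::create(_["flow"] = flow,
                      _["source_side"] = IntegerVector(side.begin(), side.end()));
}
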