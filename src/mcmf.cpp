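#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Successive shortest paths min-cost max-flow (SPFA path search).
// Capacities and costs arrive as whole-number doubles (produced by
// quantization upstream) and are carried as long long internally; all
// intermediate products stay far below 2^63. Costs must be nonnegative on
// the input arcs, which guarantees the residual network never contains a
// negative cycle and successive shortest paths yields the global optimum.
//
// [[Rcpp::export]]
List mcmf_cpp(int n_nodes, IntegerVector from, IntegerVector to,
              NumericVector capacity, NumericVector cost,
              int source, int sink) {
  const int m = from.size();
  std::vector<int> head(n_nodes, -1), nxt(2 * m), ato(2 * m);
  std::vector<long long> cap(2 * m), cst(2 * m);
  for (int e = 0; e < m; ++e) {
    if (cost[e] < 0) stop("mcmf_cpp requires nonnegative arc costs");
    int u = from[e], v = to[e];
    ato[2 * e] = v;
    cap[2 * e] = (long long) std::llround(capacity[e]);
    cst[2 * e] = (long long) std::llround(cost[e]);
    nxt[2 * e] = head[u]; head[u] = 2 * e;
    ato[2 * e + 1] = u;
    cap[2 * e + 1] = 0;
    cst[2 * e + 1] = -cst[2 * e];
    nxt[2 * e + 1] = head[v]; head[v] = 2 * e + 1;
  }
  const long long INF = std::numeric_limits<long long>::max() / 4;
  long long total_flow = 0, total_cost = 0;
  std::vector<long long> dist(n_nodes);
  std::vector<char> inq(n_nodes);
  std::vector<int> prevarc(n_nodes);
  while (true) {
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(inq.begin(), inq.end(), 0);
    std::fill(prevarc.begin(), prevarc.end(), -1);
    dist[source] = 0;
    std::deque<int> q;
    q.push_back(source);
    inq[source] = 1;
    while (!q.empty()) {
      int u = q.front(); q.pop_front(); inq[u] = 0;
      for (int a = head[u]; a != -1; a = nxt[a]) {
        int v = ato[a];
        if (cap[a] > 0 && dist[u] + cst[a] < dist[v]) {
          dist[v] = dist[u] + cst[a];
          prevarc[v] = a;
          if (!inq[v]) { inq[v] = 1; q.push_back(v); }
        }
      }
    }
    if (dist[sink] >= INF) break;
    long long push = INF;
    for (int v = sink; v != source; ) {
      int a = prevarc[v];
      push = std::min(push, cap[a]);
      v = ato[a ^ 1];
    }
    for (int v = sink; v != source; ) {
      int a = prevarc[v];
      cap[a] -= push;
      cap[a ^ 1] += push;
      v = ato[a ^ 1];
    }
    total_flow += push;
    total_cost += push * dist[sink];
  }
  NumericVector flow(m);
  for (int e = 0; e < m; ++e) flow[e] = (double) cap[2 * e + 1];
  return List::create(_["flow"] = flow,
                      _["total_flow"] = (double) total_flow,
                      _["total_cost"] = (double) total_cost);
}
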