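#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
#include <cstdint>

using namespace Rcpp;

// Successive-shortest-path min-cost flow with Dijkstra + node potentials.
// Costs must be non-negative integers (passed as doubles holding exact
// integer values <= 2^52; the R side scales real distances accordingly).
// Used for the template-matching assignment network: source -> template
// cases -> hospital rows -> fine-balance category layers -> sink.

struct Arc {
  int to;
  int64_t cap;
  int64_t cost;
  int rev; // index of reverse arc in adj[to]
};

// [[Rcpp::export]]
List mcmf_solve(int n_nodes, IntegerVector from, IntegerVector to,
                NumericVector cap, NumericVector cost,
                int source, int sink, double flow_target) {
  const int m = from.size();
  std::vector<std::vector<Arc> > adj(n_nodes);
  std::vector<std::pair<int, int> > arc_loc(m); // node, index for forward arcs

  for (int i = 0; i < m; ++i) {
    int u = from[i], v = to[i];
    if (u < 0 || u >= n_nodes || v < 0 || v >= n_nodes)
      stop("arc endpoint out of range");
    if (cost[i] < 0) stop("negative arc cost");
    Arc fwd; fwd.to = v; fwd.cap = (int64_t)cap[i];
    fwd.cost = (int64_t)cost[i]; fwd.rev = (int)adj[v].size();
    Arc bwd; bwd.to = u; bwd.cap = 0;
    bwd.cost = -(int64_t)cost[i]; bwd.rev = (int)adj[u].size();
    arc_loc[i] = std::make_pair(u, (int)adj[u].size());
    adj[u].push_back(fwd);
    adj[v].push_back(bwd);
  }

  const int64_t INF = std::numeric_limits<int64_t>::max() / 4;
  std::vector<int64_t> pot(n_nodes, 0), dist(n_nodes);
  std::vector<int> pv_node(n_nodes), pv_arc(n_nodes);
  std::vector<char> done(n_nodes);
  int64_t want = (int64_t)flow_target;
  int64_t sent = 0, total_cost = 0;

  typedef std::pair<int64_t, int> QE;
  while (sent < want) {
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(done.begin(), done.end(), 0);
    dist[source] = 0;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
    pq.push(std::make_pair((int64_t)0, source));
    while (!pq.empty()) {
      QE top = pq.top(); pq.pop();
      int u = top.second;
      if (top.first > dist[u]) continue;
      done[u] = 1;
      if (u == sink) break; // shortest path to sink is final
      for (size_t k = 0; k < adj[u].size(); ++k) {
        const Arc &a = adj[u][k];
        if (a.cap <= 0) continue;
        int64_t nd = dist[u] + a.cost + pot[u] - pot[a.to];
        if (nd < dist[a.to]) {
          dist[a.to] = nd;
          pv_node[a.to] = u;
          pv_arc[a.to] = (int)k;
          pq.push(std::make_pair(nd, a.to));
        }
      }
    }
    if (dist[sink] >= INF) break; // no augmenting path
    // potential update that keeps reduced costs nonnegative under early
    // termination: cap label contributions at the sink distance
    int64_t dsink = dist[sink];
    for (int v = 0; v < n_nodes; ++v)
      pot[v] += dist[v] < dsink ? dist[v] : dsink;
    // bottleneck along the path
    int64_t push = want - sent;
    for (int v = sink; v != source; v = pv_node[v]) {
      const Arc &a = adj[pv_node[v]][pv_arc[v]];
      if (a.cap < push) push = a.cap;
    }
    for (int v = sink; v != source; v = pv_node[v]) {
      Arc &a = adj[pv_node[v]][pv_arc[v]];
      a.cap -= push;
      adj[v][a.rev].cap += push;
      total_cost += push * a.cost;
    }
    sent += push;
  }

  NumericVector flow(m);
  for (int i = 0; i < m; ++i) {
    const Arc &a = adj[arc_loc[i].first][arc_loc[i].second];
    flow[i] = (double)((int64_t)cap[i] - a.cap);
  }
  return List::create(_["flow"] = flow,
                      _["total_cost"] = (double)total_cost,
                      _["flow_sent"] = (double)sent);
}
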