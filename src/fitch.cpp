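// Exact maximum-parsimony machinery: Fitch length evaluation on an
// explicit edge list, and branch-and-bound search over unrooted binary
// topologies with optional monophyly constraints.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstdint>
#include <functional>
using namespace Rcpp;

// Fitch per-pattern step counts for a tree given as an edge list.
// Node ids: 0..ntips-1 are tips (rows of `states`), others internal.
// The tree is rooted for evaluation on the edge incident to tip 0;
// degree-2 internal nodes are transparent. States are bitmasks over
// {A=1, C=2, G=4, T=8}; missing data = 15.
// [[Rcpp::export]]
IntegerVector fitch_eval_cpp(IntegerMatrix edges, IntegerMatrix states,
                             int nnodes) {
  const int ntips = states.nrow();
  const int npat = states.ncol();
  std::vector<std::vector<int>> adj(nnodes);
  for (int e = 0; e < edges.nrow(); ++e) {
    adj[edges(e, 0)].push_back(edges(e, 1));
    adj[edges(e, 1)].push_back(edges(e, 0));
  }
  std::vector<int> steps(npat, 0);
  std::function<std::vector<int>(int, int)> dfs = [&](int v, int parent) {
    if (v < ntips) {
      std::vector<int> s(npat);
      for (int p = 0; p < npat; ++p) s[p] = states(v, p);
      return s;
    }
    std::vector<int> acc;
    bool first = true;
    for (int u : adj[v]) {
      if (u == parent) continue;
      std::vector<int> cs = dfs(u, v);
      if (first) { acc = std::move(cs); first = false; }
      else {
        for (int p = 0; p < npat; ++p) {
          int inter = acc[p] & cs[p];
          if (inter) acc[p] = inter;
          else { acc[p] |= cs[p]; ++steps[p]; }
        }
      }
    }
    return acc;
  };
  if (adj[0].empty()) stop("tip 0 has no incident edge");
  std::vector<int> top = dfs(adj[0][0], 0);
  for (int p = 0; p < npat; ++p)
    if (!(top[p] & states(0, p))) ++steps[p];
  return wrap(steps);
}

namespace {

struct BBSearch {
  int ntax, npat;
  IntegerMatrix states;          // ntax x npat bitmasks
  NumericVector w;               // pattern weights
  std::vector<int> order;        // taxon addition order
  int mode;                      // 0 none, 1 require clade, 2 forbid clade
  uint32_t gmask;                // tip bitmask of the constrained group
  double best;
  int max_trees;
  bool overflow = false;
  std::vector<std::array<int, 2>> edges;
  std::vector<std::vector<std::array<int, 2>>> kept;
  std::vector<std::vector<int>> adj;      // scratch adjacency
  static constexpr double EPS = 1e-9;

  void build_adj(int nnodes) {
    adj.assign(nnodes, {});
    for (auto &e : edges) {
      adj[e[0]].push_back(e[1]);
      adj[e[1]].push_back(e[0]);
    }
  }

  double eval_len() {
    int nnodes = ntax + (int)edges.size() - 1;  // upper bound on ids used
    build_adj(2 * ntax);
    double total = 0.0;
    int r0 = order[0];
    std::function<std::vector<int>(int, int)> dfs = [&](int v, int parent) {
      if (v < ntax) {
        std::vector<int> s(npat);
        for (int p = 0; p < npat; ++p) s[p] = states(v, p);
        return s;
      }
      std::vector<int> acc;
      bool first = true;
      for (int u : adj[v]) {
        if (u == parent) continue;
        std::vector<int> cs = dfs(u, v);
        if (first) { acc = std::move(cs); first = false; }
        else {
          for (int p = 0; p < npat; ++p) {
            int inter = acc[p] & cs[p];
            if (inter) acc[p] = inter;
            else { acc[p] |= cs[p]; total += w[p]; }
          }
        }
      }
      return acc;
    };
    (void)nnodes;
    std::vector<int> top = dfs(adj[r0][0], r0);
    for (int p = 0; p < npat; ++p)
      if (!(top[p] & states(r0, p))) total += w[p];
    return total;
  }

  // does the complete tree contain an edge splitting exactly gmask?
  bool has_clade() {
    build_adj(2 * ntax);
    uint32_t all = 0;
    for (int k = 0; k < (int)order.size(); ++k) all |= (1u << order[k]);
    // tip mask below each directed edge via DFS from order[0]
    bool found = false;
    std::function<uint32_t(int, int)> dfs = [&](int v, int parent) {
      if (v < ntax) return (uint32_t)(1u << v);
      uint32_t m = 0;
      for (int u : adj[v]) {
        if (u == parent) continue;
        uint32_t sub = dfs(u, v);
        if (sub == gmask || (all & ~sub) == gmask) found = true;
        m |= sub;
      }
      return m;
    };
    int r0 = order[0];
    uint32_t sub = dfs(adj[r0][0], r0);
    if (sub == gmask || (all & ~sub) == gmask) found = true;
    return found;
  }

  bool constraint_ok() {
    if (mode == 0) return true;
    bool hc = has_clade();
    return mode == 1 ? hc : !hc;
  }

  void recurse(int k) {
    double len = eval_len();
    if (len > best + EPS) return;
    if (k == (int)order.size()) {
      if (!constraint_ok()) return;
      if (len < best - EPS) { best = len; kept.clear(); }
      if (std::abs(len - best) <= EPS) {
        if ((int)kept.size() < max_trees) kept.push_back(edges);
        else overflow = true;
      }
      return;
    }
    int taxon = order[k];
    int w_node = ntax + k - 2;
    int ne = (int)edges.size();
    for (int e = 0; e < ne; ++e) {
      int u = edges[e][0], v = edges[e][1];
      edges[e] = {u, w_node};
      edges.push_back({w_node, v});
      edges.push_back({w_node, taxon});
      recurse(k + 1);
      edges.pop_back();
      edges.pop_back();
      edges[e] = {u, v};
    }
  }

  // stepwise-addition greedy tree for the initial upper bound
  double greedy_len() {
    std::vector<std::array<int, 2>> saved = edges;
    for (int k = 3; k < (int)order.size(); ++k) {
      int taxon = order[k];
      int w_node = ntax + k - 2;
      int ne = (int)edges.size();
      double bestl = R_PosInf;
      int beste = 0;
      for (int e = 0; e < ne; ++e) {
        int u = edges[e][0], v = edges[e][1];
        edges[e] = {u, w_node};
        edges.push_back({w_node, v});
        edges.push_back({w_node, taxon});
        double len = eval_len();
        if (len < bestl) { bestl = len; beste = e; }
        edges.pop_back();
        edges.pop_back();
        edges[e] = {u, v};
      }
      int u = edges[beste][0], v = edges[beste][1];
      edges[beste] = {u, w_node};
      edges.push_back({w_node, v});
      edges.push_back({w_node, taxon});
    }
    double len = eval_len();
    edges = saved;
    return len;
  }
};

} // namespace

// Branch-and-bound search for all minimum-length unrooted binary trees.
// order: 0-based taxon addition order (length = ntax).
// mode: 0 unconstrained; 1 require the group monophyletic; 2 require it
// NOT monophyletic. group: 0-based tip indices.
// [[Rcpp::export]]
List bab_cpp(IntegerMatrix states, NumericVector weights, IntegerVector order,
             int mode, IntegerVector group, int max_trees) {
  BBSearch S;
  S.ntax = states.nrow();
  S.npat = states.ncol();
  if (S.ntax < 4) stop("need at least 4 taxa");
  if (S.ntax > 31) stop("too many taxa for exact search");
  S.states = states;
  S.w = weights;
  S.order.assign(order.begin(), order.end());
  S.mode = mode;
  S.gmask = 0;
  for (int i = 0; i < group.size(); ++i) S.gmask |= (1u << group[i]);
  S.max_trees = max_trees;
  S.edges = {{S.order[0], S.ntax}, {S.order[1], S.ntax}, {S.order[2], S.ntax}};
  S.best = (mode == 0) ? S.greedy_len() : R_PosInf;
  S.recurse(3);
  List trees(S.kept.size());
  for (size_t t = 0; t < S.kept.size(); ++t) {
    IntegerMatrix em(S.kept[t].size(), 2);
    for (size_t e = 0; e < S.kept[t].size(); ++e) {
      em(e, 0) = S.kept[t][e][0];
      em(e, 1) = S.kept[t][e][1];
    }
    trees[t] = em;
  }
  return List::create(_["length"] = S.best, _["trees"] = trees,
                      _["overflow"] = S.overflow);
}
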