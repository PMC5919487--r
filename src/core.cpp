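// Enumeration kernels: connected induced subgraph enumeration (ESU-style,
// exclusive-neighbourhood expansion, each subgraph visited exactly once),
// static orbit counting, and the single-edge delta counter that explores
// only the neighbourhood of the modified edge.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Lookup {
  // graphlet id per mask (-1 = disconnected) and global orbit id per
  // (mask, position), one table per subgraph size 2..5
  std::vector<int> g[6];
  std::vector<int> o[6];  // o[s][mask * s + pos]
  explicit Lookup(const List& lk) {
    for (int s = 2; s <= 5; ++s) {
      IntegerVector gv = lk[std::string("g") + char('0' + s)];
      IntegerMatrix ov = lk[std::string("o") + char('0' + s)];
      g[s].assign(gv.begin(), gv.end());
      o[s].assign((size_t)ov.nrow() * s, -1);
      for (int m = 0; m < ov.nrow(); ++m)
        for (int p = 0; p < s; ++p) o[s][(size_t)m * s + p] = ov(m, p);
    }
  }
};

struct Graph {
  int n;
  std::vector<std::vector<int>> adj;
  std::vector<uint64_t> bits;  // n x n adjacency, row-major
  Graph(int n_, const IntegerMatrix& edges) : n(n_), adj(n_) {
    bits.assign(((size_t)n * n + 63) / 64, 0);
    for (int e = 0; e < edges.nrow(); ++e) {
      int a = edges(e, 0), b = edges(e, 1);
      adj[a].push_back(b);
      adj[b].push_back(a);
      set_bit(a, b);
      set_bit(b, a);
    }
    for (auto& v : adj) std::sort(v.begin(), v.end());
  }
  void set_bit(int i, int j) {
    size_t idx = (size_t)i * n + j;
    bits[idx >> 6] |= (uint64_t)1 << (idx & 63);
  }
  void clear_bit(int i, int j) {
    size_t idx = (size_t)i * n + j;
    bits[idx >> 6] &= ~((uint64_t)1 << (idx & 63));
  }
  bool has(int i, int j) const {
    size_t idx = (size_t)i * n + j;
    return (bits[idx >> 6] >> (idx & 63)) & 1;
  }
};

// pair rank for 0-based positions i < j among size-s tuple
inline int pair_rank(int i, int j, int s) {
  return i * s - (i * (i + 1)) / 2 + (j - i - 1);
}

// mask of the induced subgraph on sorted positions sub[0..s-1]
inline int mask_of(const Graph& G, const int* sub, int s) {
  int mask = 0, r = 0;
  for (int i = 0; i < s; ++i)
    for (int j = i + 1; j < s; ++j, ++r)
      if (G.has(sub[i], sub[j])) mask |= 1 << r;
  return mask;
}

struct CountAcc {
  std::vector<long long> counts;  // n x 73 row-major
  std::vector<long long> totals;  // 30
  long long visited = 0;
  int n;
  explicit CountAcc(int n_) : counts((size_t)n_ * 73, 0), totals(30, 0), n(n_) {}
  void add(const Lookup& L, const Graph& G, const int* sub, int s, int sign) {
    int mask = mask_of(G, sub, s);
    int gid = L.g[s][mask];
    if (gid < 0) return;  // cannot happen for ESU sets, kept for safety
    totals[gid] += sign;
    const int* orb = &L.o[s][(size_t)mask * s];
    for (int p = 0; p < s; ++p) counts[(size_t)sub[p] * 73 + orb[p]] += sign;
  }
};

// ESU: enumerate every connected induced subgraph of size 2..5 exactly once.
// S holds the current subgraph; ext is the extension list (exclusive
// neighbours with id > root, in discovery order); blocked marks nodes in
// S or already placed in an extension list along the current branch.
void esu_recurse(const Graph& G, const Lookup& L, CountAcc& acc, int root,
                 std::vector<int>& S, std::vector<int>& ext,
                 std::vector<char>& blocked) {
  int s = (int)S.size();
  if (s >= 2) {
    ++acc.visited;
    std::vector<int> sub(S);
    std::sort(sub.begin(), sub.end());
    acc.add(L, G, sub.data(), s, +1);
  }
  if (s == 5) return;
  // branch on each extension node; later branches exclude earlier ones
  for (size_t i = 0; i < ext.size(); ++i) {
    int w = ext[i];
    std::vector<int> next(ext.begin() + i + 1, ext.end());
    std::vector<int> newly;
    for (int u : G.adj[w])
      if (u > root && !blocked[u]) {
        newly.push_back(u);
        blocked[u] = 1;
        next.push_back(u);
      }
    S.push_back(w);
    esu_recurse(G, L, acc, root, S, next, blocked);
    S.pop_back();
    for (int u : newly) blocked[u] = 0;
  }
}

void count_all_into(const Graph& G, const Lookup& L, CountAcc& acc) {
  std::vector<char> blocked(G.n, 0);
  for (int v = 0; v < G.n; ++v) {
    std::vector<int> S{v}, ext;
    blocked[v] = 1;
    for (int u : G.adj[v])
      if (u > v) {
        ext.push_back(u);
        blocked[u] = 1;
      }
    esu_recurse(G, L, acc, v, S, ext, blocked);
    blocked[v] = 0;
    for (int u : ext) blocked[u] = 0;
  }
}

// Delta enumeration: every connected induced subgraph of the edge-present
// graph containing both u and v, exactly once (ESU rooted at the pair).
struct DeltaAcc {
  std::vector<long long> counts;
  std::vector<long long> totals;
  long long visited = 0;
  bool collect;
  std::vector<std::vector<int>> sets;
  explicit DeltaAcc(int n, bool collect_) : counts((size_t)n * 73, 0),
    totals(30, 0), collect(collect_) {}
};

void delta_classify(const Graph& G, const Lookup& L, DeltaAcc& acc,
                    const int* sub, int s, int u, int v, int sign_add) {
  // sign_add = +1 for ADD (with-edge state is "after"), -1 for REMOVE
  int mask_with = mask_of(G, sub, s);
  int pu = -1, pv = -1;
  for (int p = 0; p < s; ++p) {
    if (sub[p] == u) pu = p;
    if (sub[p] == v) pv = p;
  }
  int bit = pair_rank(std::min(pu, pv), std::max(pu, pv), s);
  int mask_without = mask_with & ~(1 << bit);
  int g_with = L.g[s][mask_with];
  int g_without = L.g[s][mask_without];
  // with-edge state
  acc.totals[g_with] += sign_add;
  const int* ow = &L.o[s][(size_t)mask_with * s];
  for (int p = 0; p < s; ++p) acc.counts[(size_t)sub[p] * 73 + ow[p]] += sign_add;
  // without-edge state (skip when disconnected: contributes nothing)
  if (g_without >= 0) {
    acc.totals[g_without] -= sign_add;
    const int* oo = &L.o[s][(size_t)mask_without * s];
    for (int p = 0; p < s; ++p) acc.counts[(size_t)sub[p] * 73 + oo[p]] -= sign_add;
  }
}

void delta_recurse(const Graph& G, const Lookup& L, DeltaAcc& acc,
                   std::vector<int>& S, std::vector<int>& ext,
                   std::vector<char>& blocked, int u, int v, int sign_add) {
  int s = (int)S.size();
  ++acc.visited;
  {
    std::vector<int> sub(S);
    std::sort(sub.begin(), sub.end());
    if (acc.collect) acc.sets.push_back(sub);
    delta_classify(G, L, acc, sub.data(), s, u, v, sign_add);
  }
  if (s == 5) return;
  for (size_t i = 0; i < ext.size(); ++i) {
    int w = ext[i];
    std::vector<int> next(ext.begin() + i + 1, ext.end());
    std::vector<int> newly;
    for (int x : G.adj[w])
      if (!blocked[x]) {
        newly.push_back(x);
        blocked[x] = 1;
        next.push_back(x);
      }
    S.push_back(w);
    delta_recurse(G, L, acc, S, next, blocked, u, v, sign_add);
    S.pop_back();
    for (int x : newly) blocked[x] = 0;
  }
}

void delta_into(const Graph& Gp, const Lookup& L, DeltaAcc& acc,
                int u, int v, int sign_add) {
  std::vector<char> blocked(Gp.n, 0);
  std::vector<int> S{u, v}, ext;
  blocked[u] = blocked[v] = 1;
  for (int x : Gp.adj[u])
    if (!blocked[x]) {
      blocked[x] = 1;
      ext.push_back(x);
    }
  for (int x : Gp.adj[v])
    if (!blocked[x]) {
      blocked[x] = 1;
      ext.push_back(x);
    }
  delta_recurse(Gp, L, acc, S, ext, blocked, u, v, sign_add);
}

List sparse_from(const std::vector<long long>& counts,
                 const std::vector<long long>& totals, int n,
                 long long visited) {
  std::vector<int> ni, oi;
  std::vector<double> val;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 73; ++j) {
      long long c = counts[(size_t)i * 73 + j];
      if (c != 0) {
        ni.push_back(i);
        oi.push_back(j);
        val.push_back((double)c);
      }
    }
  return List::create(_["node"] = wrap(ni), _["orbit"] = wrap(oi),
                      _["delta"] = wrap(val),
                      _["totals"] = NumericVector(totals.begin(), totals.end()),
                      _["visited"] = (double)visited);
}

}  // namespace

// [[Rcpp::export]]
List cpp_count_all(int n, IntegerMatrix edges, List lookup) {
  Lookup L(lookup);
  Graph G(n, edges);
  CountAcc acc(n);
  count_all_into(G, L, acc);
  NumericMatrix cm(n, 73);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 73; ++j) cm(i, j) = (double)acc.counts[(size_t)i * 73 + j];
  return List::create(_["counts"] = cm,
                      _["totals"] = NumericVector(acc.totals.begin(),
                                                  acc.totals.end()),
                      _["visited"] = (double)acc.visited);
}

// [[Rcpp::export]]
List cpp_delta(int n, IntegerMatrix edges_present, int u, int v, bool is_add,
               bool collect_sets, List lookup) {
  // edges_present: edge list of the edge-present graph (G' for ADD, G for
  // REMOVE); must contain (u, v)
  Lookup L(lookup);
  Graph Gp(n, edges_present);
  DeltaAcc acc(n, collect_sets);
  delta_into(Gp, L, acc, u, v, is_add ? +1 : -1);
  List out = sparse_from(acc.counts, acc.totals, n, acc.visited);
  if (collect_sets) {
    List sl(acc.sets.size());
    for (size_t i = 0; i < acc.sets.size(); ++i) sl[i] = wrap(acc.sets[i]);
    out["sets"] = sl;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_penalty_increases(int n, IntegerMatrix edges,
                                    IntegerMatrix candidates,
                                    NumericVector redundancy, List lookup) {
  // redundancy-penalty increase of adding each absent candidate edge,
  // evaluated against the same base graph (no mutation)
  Lookup L(lookup);
  Graph G(n, edges);
  NumericVector out(candidates.nrow());
  for (int c = 0; c < candidates.nrow(); ++c) {
    int u = candidates(c, 0), v = candidates(c, 1);
    // toggle the candidate edge in place (neighbour-list order is
    // irrelevant to the enumeration; membership tests use the bit matrix)
    G.adj[u].push_back(v);
    G.adj[v].push_back(u);
    G.set_bit(u, v);
    G.set_bit(v, u);
    DeltaAcc acc(n, false);
    delta_into(G, L, acc, u, v, +1);
    double s = 0;
    for (int g = 0; g < 30; ++g) s += acc.totals[g] * redundancy[g];
    out[c] = s;
    G.adj[u].pop_back();
    G.adj[v].pop_back();
    G.clear_bit(u, v);
    G.clear_bit(v, u);
  }
  return out;
}
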