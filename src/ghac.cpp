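// Compiled kernels: closed-trail distances via Suurballe's algorithm
// (minimum-cost pair of edge-disjoint paths), maximal-clique search for
// overlap weights, and the clique-agglomeration inner loop.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
#include <algorithm>
#include <limits>
#include <cmath>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Graph scaffolding: undirected edges stored once, traversed as two arcs.
// ---------------------------------------------------------------------------
struct AdjGraph {
  int n;
  std::vector<int> ea, eb;          // edge endpoints, 0-based
  std::vector<double> cost;         // positive arc cost (same both directions)
  std::vector<std::vector<std::pair<int,int>>> adj; // node -> (neighbour, edge id)

  AdjGraph(int n_, const IntegerVector& u, const IntegerVector& v,
           const NumericVector& c) : n(n_) {
    int m = u.size();
    ea.resize(m); eb.resize(m); cost.resize(m);
    adj.assign(n, {});
    for (int e = 0; e < m; ++e) {
      ea[e] = u[e]; eb[e] = v[e]; cost[e] = c[e];
      adj[ea[e]].push_back({eb[e], e});
      adj[eb[e]].push_back({ea[e], e});
    }
  }
};

typedef std::pair<double,int> QItem; // (distance, node)

// Standard Dijkstra from s; fills dist, parent node and parent edge.
static void dijkstra(const AdjGraph& g, int s, std::vector<double>& dist,
                     std::vector<int>& pn, std::vector<int>& pe) {
  dist.assign(g.n, INF); pn.assign(g.n, -1); pe.assign(g.n, -1);
  std::priority_queue<QItem, std::vector<QItem>, std::greater<QItem>> pq;
  dist[s] = 0.0; pq.push({0.0, s});
  while (!pq.empty()) {
    QItem top = pq.top(); pq.pop();
    double d = top.first; int u = top.second;
    if (d > dist[u]) continue;
    for (auto& nb : g.adj[u]) {
      int v = nb.first, e = nb.second;
      double nd = d + g.cost[e];
      if (nd < dist[v]) { dist[v] = nd; pn[v] = u; pe[v] = e; pq.push({nd, v}); }
    }
  }
}

// Second (residual) Dijkstra with reduced costs after reserving the shortest
// path; p1dir[e] = +1 if the first path traverses e as ea->eb, -1 if eb->ea,
// 0 if unused.  Arcs along the first path's direction are closed; the
// opposite (cancellation) arcs have reduced cost zero.
static double dijkstra_residual(const AdjGraph& g, int s, int t,
                                const std::vector<double>& pot,
                                const std::vector<int>& p1dir,
                                std::vector<int>* pn2, std::vector<int>* pe2) {
  std::vector<double> dist(g.n, INF);
  if (pn2) { pn2->assign(g.n, -1); pe2->assign(g.n, -1); }
  std::priority_queue<QItem, std::vector<QItem>, std::greater<QItem>> pq;
  dist[s] = 0.0; pq.push({0.0, s});
  while (!pq.empty()) {
    QItem top = pq.top(); pq.pop();
    double d = top.first; int u = top.second;
    if (d > dist[u]) continue;
    if (u == t) break;
    for (auto& nb : g.adj[u]) {
      int v = nb.first, e = nb.second;
      if (pot[v] == INF) continue;  // unreachable in base graph
      int dir = (u == g.ea[e]) ? 1 : -1;
      double rc;
      if (p1dir[e] != 0) {
        if (p1dir[e] == dir) continue;          // capacity used up
        rc = 0.0;                                // cancellation arc
      } else {
        rc = g.cost[e] + pot[u] - pot[v];
        if (rc < 0.0) rc = 0.0;                  // guard fp noise
      }
      double nd = d + rc;
      if (nd < dist[v]) {
        dist[v] = nd;
        if (pn2) { (*pn2)[v] = u; (*pe2)[v] = e; }
        pq.push({nd, v});
      }
    }
  }
  return dist[t];
}

// Mark the tree path s->t into p1dir (+1 = traversed ea->eb).  Returns false
// if t unreachable.
static bool mark_tree_path(const AdjGraph& g, int s, int t,
                           const std::vector<int>& pn, const std::vector<int>& pe,
                           std::vector<int>& p1dir, std::vector<int>* edges_out) {
  if (pn[t] < 0 && t != s) return false;
  int v = t;
  while (v != s) {
    int e = pe[v], u = pn[v];
    p1dir[e] = (u == g.ea[e]) ? 1 : -1;
    if (edges_out) edges_out->push_back(e);
    v = u;
  }
  return true;
}

// [[Rcpp::export(name = ".wct_matrix_cpp")]]
NumericMatrix wct_matrix_cpp(int n, IntegerVector eu, IntegerVector ev,
                             NumericVector cost) {
  AdjGraph g(n, eu, ev, cost);
  NumericMatrix D(n, n);
  std::vector<double> dist; std::vector<int> pn, pe;
  std::vector<int> p1dir(g.ea.size(), 0), touched;
  for (int s = 0; s < n - 1; ++s) {
    dijkstra(g, s, dist, pn, pe);
    for (int t = s + 1; t < n; ++t) {
      double total = INF;
      if (dist[t] < INF) {
        touched.clear();
        mark_tree_path(g, s, t, pn, pe, p1dir, &touched);
        double d2r = dijkstra_residual(g, s, t, dist, p1dir, nullptr, nullptr);
        if (d2r < INF) total = 2.0 * dist[t] + d2r;
        for (int e : touched) p1dir[e] = 0;
      }
      D(s, t) = total; D(t, s) = total;
    }
    Rcpp::checkUserInterrupt();
  }
  return D;
}

// Single-pair Suurballe returning the two edge-disjoint paths as node
// sequences (0-based), or infeasible marker.
// [[Rcpp::export(name = ".suurballe_pair_cpp")]]
List suurballe_pair_cpp(int n, IntegerVector eu, IntegerVector ev,
                        NumericVector cost, int s, int t) {
  AdjGraph g(n, eu, ev, cost);
  std::vector<double> dist; std::vector<int> pn, pe;
  dijkstra(g, s, dist, pn, pe);
  if (dist[t] == INF)
    return List::create(_["cost"] = R_PosInf, _["feasible"] = false);
  std::vector<int> p1dir(g.ea.size(), 0);
  mark_tree_path(g, s, t, pn, pe, p1dir, nullptr);
  std::vector<int> pn2, pe2;
  double d2r = dijkstra_residual(g, s, t, dist, p1dir, &pn2, &pe2);
  if (d2r == INF)
    return List::create(_["cost"] = R_PosInf, _["feasible"] = false);
  double total = 2.0 * dist[t] + d2r;

  // Combine arc sets, cancelling opposed traversals of the same edge.
  std::vector<int> use(g.ea.size(), 0); // net direction per edge
  for (size_t e = 0; e < use.size(); ++e) use[e] = p1dir[e];
  {
    int v = t;
    while (v != s) {
      int e = pe2[v], u = pn2[v];
      int dir = (u == g.ea[e]) ? 1 : -1;
      use[e] = (use[e] == -dir) ? 0 : dir;  // cancel or adopt
      v = u;
    }
  }
  // Out-arc lists of the 2-unit flow; walk two trails s -> t.
  std::vector<std::vector<std::pair<int,int>>> out(n);
  for (size_t e = 0; e < use.size(); ++e) {
    if (use[e] == 1) out[g.ea[e]].push_back({g.eb[e], (int)e});
    else if (use[e] == -1) out[g.eb[e]].push_back({g.ea[e], (int)e});
  }
  List paths(2);
  for (int k = 0; k < 2; ++k) {
    std::vector<int> walk; walk.push_back(s);
    int v = s;
    while (v != t || walk.size() == 1) {
      if (out[v].empty()) break;  // defensive; cannot happen for valid flow
      auto nb = out[v].back(); out[v].pop_back();
      v = nb.first; walk.push_back(v);
      if (v == t) break;
    }
    paths[k] = IntegerVector(walk.begin(), walk.end());
  }
  return List::create(_["cost"] = total, _["feasible"] = true,
                      _["paths"] = paths);
}

// ---------------------------------------------------------------------------
// Maximal cliques (Bron-Kerbosch with pivoting) on an induced subset, used
// to weight cluster overlaps: w(Q) = |Q| + sum_{e in Q} w(e) / wtotal.
// ---------------------------------------------------------------------------
struct OverlapScorer {
  const NumericMatrix& W;   // full weighted adjacency
  double wtotal;
  std::vector<int> sub;     // subset vertex ids (0-based into W)
  std::vector<std::vector<char>> A;   // induced adjacency
  double best;

  OverlapScorer(const NumericMatrix& W_, double wt) : W(W_), wtotal(wt), best(0.0) {}

  double clique_value(const std::vector<int>& Q) const {
    double wsum = 0.0;
    for (size_t i = 0; i < Q.size(); ++i)
      for (size_t j = i + 1; j < Q.size(); ++j)
        wsum += W(sub[Q[i]], sub[Q[j]]);
    return (double)Q.size() + wsum / wtotal;
  }

  void bk(std::vector<int>& R, std::vector<int> P, std::vector<int> X) {
    if (P.empty() && X.empty()) {
      if (R.size() >= 2) { double v = clique_value(R); if (v > best) best = v; }
      return;
    }
    // pivot: vertex of P u X with most neighbours in P
    int pivot = -1, bestdeg = -1;
    for (int u : P) { int d = 0; for (int w : P) if (A[u][w]) ++d; if (d > bestdeg) { bestdeg = d; pivot = u; } }
    for (int u : X) { int d = 0; for (int w : P) if (A[u][w]) ++d; if (d > bestdeg) { bestdeg = d; pivot = u; } }
    std::vector<int> cand;
    for (int v : P) if (pivot < 0 || !A[pivot][v]) cand.push_back(v);
    for (int v : cand) {
      std::vector<int> P2, X2;
      for (int w : P) if (A[v][w]) P2.push_back(w);
      for (int w : X) if (A[v][w]) X2.push_back(w);
      R.push_back(v);
      bk(R, P2, X2);
      R.pop_back();
      P.erase(std::find(P.begin(), P.end(), v));
      X.push_back(v);
    }
  }

  double run(const std::vector<int>& subset) {
    sub = subset;
    int k = sub.size();
    if (k < 2) return 0.0;
    A.assign(k, std::vector<char>(k, 0));
    bool any_edge = false;
    for (int i = 0; i < k; ++i)
      for (int j = i + 1; j < k; ++j)
        if (W(sub[i], sub[j]) > 0) { A[i][j] = A[j][i] = 1; any_edge = true; }
    if (!any_edge) return 0.0;
    best = 0.0;
    std::vector<int> R, P(k), X;
    for (int i = 0; i < k; ++i) P[i] = i;
    bk(R, P, X);
    return best;
  }
};

// [[Rcpp::export(name = ".max_overlap_clique_weight_cpp")]]
double max_overlap_clique_weight_cpp(NumericMatrix W, IntegerVector subset,
                                     double wtotal) {
  OverlapScorer sc(W, wtotal);
  std::vector<int> sub(subset.begin(), subset.end());
  return sc.run(sub);
}

// ---------------------------------------------------------------------------
// Cluster dissimilarities and agglomeration.
// ---------------------------------------------------------------------------
static double cluster_dissimilarity(const NumericMatrix& D, const NumericMatrix& W,
                                    const std::vector<int>& a, const std::vector<int>& b,
                                    int linkage, double wtotal, bool paircount,
                                    OverlapScorer& sc,
                                    std::map<std::vector<int>, double>& cache) {
  std::vector<int> exA, exB, ov;
  std::set_difference(a.begin(), a.end(), b.begin(), b.end(), std::back_inserter(exA));
  std::set_difference(b.begin(), b.end(), a.begin(), a.end(), std::back_inserter(exB));
  if (exA.empty() || exB.empty()) return 0.0;  // nested clusters
  std::set_intersection(a.begin(), a.end(), b.begin(), b.end(), std::back_inserter(ov));
  double ovw = 0.0;
  if (ov.size() >= 2) {
    auto hit = cache.find(ov);
    if (hit != cache.end()) ovw = hit->second;
    else { ovw = sc.run(ov); cache[ov] = ovw; }
  }
  double denom = 1.0 + ovw;
  if (linkage == 0) {                       // complete linkage
    double mx = 0.0;
    for (int i : exA) for (int j : exB) { double d = D(i, j); if (d > mx) mx = d; }
    return mx / denom;
  }
  double sm = 0.0;                          // average linkage
  for (int i : exA) for (int j : exB) sm += D(i, j);
  double sz = paircount ? (double)exA.size() * (double)exB.size()
                        : (double)(exA.size() + exB.size());
  return sm / (sz * denom);
}

// [[Rcpp::export(name = ".dissimilarity_cpp")]]
double dissimilarity_cpp(NumericMatrix D, NumericMatrix W, IntegerVector a,
                         IntegerVector b, int linkage, double wtotal,
                         bool paircount) {
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  std::sort(av.begin(), av.end()); std::sort(bv.begin(), bv.end());
  OverlapScorer sc(W, wtotal);
  std::map<std::vector<int>, double> cache;
  return cluster_dissimilarity(D, W, av, bv, linkage, wtotal, paircount, sc, cache);
}

// Greedy agglomeration over clique base elements.  Cluster ids are 0-based:
// base cliques 0..K-1, merged clusters K, K+1, ...  Ties on dissimilarity
// break by the lexicographically smallest (min id, max id) pair.
// [[Rcpp::export(name = ".agglomerate_cpp")]]
List agglomerate_cpp(NumericMatrix D, NumericMatrix W, List cliques,
                     int linkage, double wtotal, bool paircount) {
  int K = cliques.size();
  if (K <= 1)
    return List::create(_["left"] = IntegerVector(0), _["right"] = IntegerVector(0),
                        _["height"] = NumericVector(0), _["newid"] = IntegerVector(0));
  std::vector<std::vector<int>> verts(K);
  for (int i = 0; i < K; ++i) {
    IntegerVector q = cliques[i];
    verts[i] = std::vector<int>(q.begin(), q.end());
    std::sort(verts[i].begin(), verts[i].end());
  }
  std::vector<int> id(K);       // cluster id per slot
  std::vector<char> alive(K, 1);
  for (int i = 0; i < K; ++i) id[i] = i;

  OverlapScorer sc(W, wtotal);
  std::map<std::vector<int>, double> cache;
  std::vector<double> dmat((size_t)K * K, INF);
  auto dm = [&](int i, int j) -> double& { return dmat[(size_t)i * K + j]; };

  auto better = [&](double v1, int p1a, int p1b, double v2, int p2a, int p2b) {
    // is candidate 1 (value v1, id pair p1) preferable to candidate 2?
    if (v1 != v2) return v1 < v2;
    int lo1 = std::min(p1a, p1b), hi1 = std::max(p1a, p1b);
    int lo2 = std::min(p2a, p2b), hi2 = std::max(p2a, p2b);
    if (lo1 != lo2) return lo1 < lo2;
    return hi1 < hi2;
  };

  for (int i = 0; i < K; ++i)
    for (int j = i + 1; j < K; ++j) {
      double d = cluster_dissimilarity(D, W, verts[i], verts[j], linkage,
                                       wtotal, paircount, sc, cache);
      dm(i, j) = d; dm(j, i) = d;
    }

  // nearest-neighbour bookkeeping per slot
  std::vector<int> nns(K, -1);
  auto rescan = [&](int i) {
    int bestj = -1;
    for (int j = 0; j < K; ++j) {
      if (j == i || !alive[j]) continue;
      if (bestj < 0 || better(dm(i, j), id[i], id[j], dm(i, bestj), id[i], id[bestj]))
        bestj = j;
    }
    nns[i] = bestj;
  };
  for (int i = 0; i < K; ++i) rescan(i);

  int nm = K - 1;
  IntegerVector left(nm), right(nm), newid(nm);
  NumericVector height(nm);

  for (int step = 0; step < nm; ++step) {
    int bi = -1;
    for (int i = 0; i < K; ++i) {
      if (!alive[i] || nns[i] < 0) continue;
      int j = nns[i];
      if (bi < 0 || better(dm(i, j), id[i], id[j], dm(bi, nns[bi]), id[bi], id[nns[bi]]))
        bi = i;
    }
    int a = bi, b = nns[bi];
    int sa = std::min(a, b), sb = std::max(a, b);
    left[step] = std::min(id[a], id[b]);
    right[step] = std::max(id[a], id[b]);
    height[step] = dm(a, b);
    int nid = K + step;
    newid[step] = nid;

    std::vector<int> merged;
    std::set_union(verts[sa].begin(), verts[sa].end(), verts[sb].begin(),
                   verts[sb].end(), std::back_inserter(merged));
    verts[sa] = std::move(merged);
    verts[sb].clear();
    alive[sb] = 0; id[sa] = nid;

    for (int j = 0; j < K; ++j) {
      if (!alive[j] || j == sa) continue;
      double d = cluster_dissimilarity(D, W, verts[sa], verts[j], linkage,
                                       wtotal, paircount, sc, cache);
      dm(sa, j) = d; dm(j, sa) = d;
    }
    rescan(sa);
    for (int j = 0; j < K; ++j) {
      if (!alive[j] || j == sa) continue;
      if (nns[j] == sa || nns[j] == sb) rescan(j);
      else if (better(dm(j, sa), id[j], id[sa], dm(j, nns[j]), id[j], id[nns[j]]))
        nns[j] = sa;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["left"] = left, _["right"] = right,
                      _["height"] = height, _["newid"] = newid);
}
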