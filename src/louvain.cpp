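#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <vector>
using namespace Rcpp;

// Louvain modularity maximisation on an undirected weighted graph, with
// seeded restarts and a greedy refinement phase (node sweeps on the original
// graph + community pair merges). Randomness: node processing order drawn
// from R's RNG, so set.seed() in R fully determines the result.

namespace {

struct WGraph {
  int n;
  std::vector<std::vector<std::pair<int, double> > > adj;  // no self loops
  std::vector<double> selfw;                               // self-loop weight
  std::vector<double> deg;                                 // strength incl. 2*selfw
  double m2;                                               // total strength

  void build(int n_, const std::vector<int>& ei, const std::vector<int>& ej,
             const std::vector<double>& w) {
    n = n_;
    adj.assign(n, std::vector<std::pair<int, double> >());
    selfw.assign(n, 0.0);
    for (size_t e = 0; e < ei.size(); ++e) {
      if (ei[e] == ej[e]) {
        selfw[ei[e]] += w[e];
      } else {
        adj[ei[e]].push_back(std::make_pair(ej[e], w[e]));
        adj[ej[e]].push_back(std::make_pair(ei[e], w[e]));
      }
    }
    deg.assign(n, 0.0);
    m2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 2.0 * selfw[i];
      for (size_t q = 0; q < adj[i].size(); ++q) s += adj[i][q].second;
      deg[i] = s;
      m2 += s;
    }
  }
};

// One local-move phase; comm modified in place (labels arbitrary ints >= 0).
// Considers moves to neighbouring communities and isolation. Returns true if
// any node moved.
bool local_moves(const WGraph& g, std::vector<int>& comm,
                 const std::vector<int>& order, double eps) {
  std::vector<double> ctot(2 * g.n, 0.0);  // room for fresh singleton labels
  int next_free = 0;
  for (int i = 0; i < g.n; ++i) {
    ctot[comm[i]] += g.deg[i];
    next_free = std::max(next_free, comm[i] + 1);
  }
  std::map<int, double> wc;
  bool any_moved = false;
  bool moved = true;
  while (moved) {
    moved = false;
    for (size_t oi = 0; oi < order.size(); ++oi) {
      const int i = order[oi];
      if (g.adj[i].empty()) continue;
      const int ci = comm[i];
      wc.clear();
      for (size_t q = 0; q < g.adj[i].size(); ++q)
        wc[comm[g.adj[i][q].first]] += g.adj[i][q].second;
      ctot[ci] -= g.deg[i];
      std::map<int, double>::const_iterator it = wc.find(ci);
      const double wbase = (it == wc.end()) ? 0.0 : it->second;
      double best_g = wbase - ctot[ci] * g.deg[i] / g.m2;
      int best_c = ci;
      if (0.0 > best_g + eps) { best_g = 0.0; best_c = -1; }  // isolation
      for (it = wc.begin(); it != wc.end(); ++it) {
        if (it->first == ci) continue;
        const double gn = it->second - ctot[it->first] * g.deg[i] / g.m2;
        if (gn > best_g + eps) { best_g = gn; best_c = it->first; }
      }
      if (best_c == -1) {
        best_c = next_free++;
        if (best_c >= (int)ctot.size()) ctot.resize(best_c + 1, 0.0);
      }
      ctot[best_c] += g.deg[i];
      if (best_c != ci) { comm[i] = best_c; moved = true; any_moved = true; }
    }
  }
  return any_moved;
}

// relabel communities to 0..C-1 in order of first appearance
int compress(std::vector<int>& comm) {
  std::map<int, int> remap;
  int next = 0;
  for (size_t i = 0; i < comm.size(); ++i) {
    std::map<int, int>::iterator it = remap.find(comm[i]);
    if (it == remap.end()) { remap[comm[i]] = next; comm[i] = next++; }
    else comm[i] = it->second;
  }
  return next;
}

double modularity_of(const WGraph& g, const std::vector<int>& comm, int C) {
  std::vector<double> win(C, 0.0), ctot(C, 0.0);
  for (int i = 0; i < g.n; ++i) {
    ctot[comm[i]] += g.deg[i];
    win[comm[i]] += 2.0 * g.selfw[i];
    for (size_t q = 0; q < g.adj[i].size(); ++q)
      if (comm[g.adj[i][q].first] == comm[i]) win[comm[i]] += g.adj[i][q].second;
  }
  double q = 0.0;
  for (int c = 0; c < C; ++c)
    q += win[c] / g.m2 - (ctot[c] / g.m2) * (ctot[c] / g.m2);
  return q;
}

std::vector<int> shuffled_order(int n) {
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  // Fisher-Yates using R's RNG
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(ord[i], ord[j]);
  }
  return ord;
}

// greedy community pair merges on g until no merge increases modularity;
// returns true if anything merged
bool merge_pass(const WGraph& g, std::vector<int>& comm, double eps) {
  bool merged_any = false;
  for (;;) {
    int C = compress(comm);
    if (C < 2) return merged_any;
    std::vector<double> ctot(C, 0.0);
    for (int i = 0; i < g.n; ++i) ctot[comm[i]] += g.deg[i];
    std::map<std::pair<int, int>, double> between;
    for (int i = 0; i < g.n; ++i)
      for (size_t q = 0; q < g.adj[i].size(); ++q) {
        const int j = g.adj[i][q].first;
        if (j <= i) continue;
        const int a = std::min(comm[i], comm[j]), b = std::max(comm[i], comm[j]);
        if (a != b) between[std::make_pair(a, b)] += g.adj[i][q].second;
      }
    double best_gain = eps;
    std::pair<int, int> best(-1, -1);
    for (std::map<std::pair<int, int>, double>::const_iterator it = between.begin();
         it != between.end(); ++it) {
      const double gain = 2.0 * it->second / g.m2 -
        2.0 * ctot[it->first.first] * ctot[it->first.second] / (g.m2 * g.m2);
      if (gain > best_gain) { best_gain = gain; best = it->first; }
    }
    if (best.first < 0) return merged_any;
    for (int i = 0; i < g.n; ++i)
      if (comm[i] == best.second) comm[i] = best.first;
    merged_any = true;
  }
}

// gain of moving node i from its community a to community b (b may equal -1
// for a fresh singleton); ctot_a includes i's strength
inline double move_gain(const WGraph& g, int i, double w_ia, double w_ib,
                        double ctot_a, double ctot_b) {
  return 2.0 * (w_ib - w_ia) / g.m2 -
         2.0 * g.deg[i] * (ctot_b - ctot_a + g.deg[i]) / (g.m2 * g.m2);
}

// weight from node i to community c (excluding i itself)
inline double weight_to(const WGraph& g, const std::vector<int>& comm,
                        int i, int c) {
  double s = 0.0;
  for (size_t q = 0; q < g.adj[i].size(); ++q)
    if (comm[g.adj[i][q].first] == c) s += g.adj[i][q].second;
  return s;
}

// Kernighan-Lin style chain pass: repeatedly apply the single best move
// (possibly worsening), locking each moved node, and keep the best prefix.
// Exact incremental gains; cost O(n^2 * deg) so intended for small graphs.
bool kl_pass(const WGraph& g, std::vector<int>& comm, double eps) {
  const int n = g.n;
  std::vector<double> ctot(2 * n + 1, 0.0);
  int next_free = 0;
  for (int i = 0; i < n; ++i) {
    ctot[comm[i]] += g.deg[i];
    next_free = std::max(next_free, comm[i] + 1);
  }
  std::vector<int> cur = comm, best_comm = comm;
  std::vector<bool> locked(n, false);
  double q_rel = 0.0, best_rel = 0.0;  // modularity relative to entry
  bool improved = false;
  for (int step = 0; step < n; ++step) {
    double bg = -R_PosInf;
    int bi = -1, bt = -1;
    for (int i = 0; i < n; ++i) {
      if (locked[i] || g.adj[i].empty()) continue;
      const int a = cur[i];
      std::map<int, double> wc;
      for (size_t q = 0; q < g.adj[i].size(); ++q)
        wc[cur[g.adj[i][q].first]] += g.adj[i][q].second;
      const double w_ia = wc.count(a) ? wc[a] : 0.0;
      // isolation target
      double gain = move_gain(g, i, w_ia, 0.0, ctot[a], 0.0);
      if (gain > bg) { bg = gain; bi = i; bt = -1; }
      for (std::map<int, double>::const_iterator it = wc.begin();
           it != wc.end(); ++it) {
        if (it->first == a) continue;
        gain = move_gain(g, i, w_ia, it->second, ctot[a], ctot[it->first]);
        if (gain > bg) { bg = gain; bi = i; bt = it->first; }
      }
    }
    if (bi < 0) break;
    int target = bt;
    if (target == -1) {
      target = next_free++;
      if (target >= (int)ctot.size()) ctot.resize(target + 1, 0.0);
    }
    ctot[cur[bi]] -= g.deg[bi];
    ctot[target] += g.deg[bi];
    cur[bi] = target;
    locked[bi] = true;
    q_rel += bg;
    if (q_rel > best_rel + eps) {
      best_rel = q_rel;
      best_comm = cur;
      improved = true;
    }
  }
  if (improved) comm = best_comm;
  return improved;
}

// all-pairs node swap pass: exchange the communities of two nodes when that
// increases modularity. Exact gains; O(n^2 * deg) per sweep, small graphs.
bool swap_pass(const WGraph& g, std::vector<int>& comm, double eps) {
  const int n = g.n;
  std::vector<double> ctot(2 * n + 1, 0.0);
  for (int i = 0; i < n; ++i) ctot[comm[i]] += g.deg[i];
  bool any = false;
  bool moved = true;
  while (moved) {
    moved = false;
    for (int i = 0; i < n - 1; ++i) {
      if (g.adj[i].empty()) continue;
      for (int j = i + 1; j < n; ++j) {
        const int a = comm[i], b = comm[j];
        if (a == b || g.adj[j].empty()) continue;
        double w_ij = 0.0;
        for (size_t q = 0; q < g.adj[i].size(); ++q)
          if (g.adj[i][q].first == j) w_ij += g.adj[i][q].second;
        const double w_ia = weight_to(g, comm, i, a);
        const double w_ib = weight_to(g, comm, i, b);
        const double g1 = move_gain(g, i, w_ia, w_ib, ctot[a], ctot[b]);
        // state after i -> b
        const double ctot_a1 = ctot[a] - g.deg[i];
        const double ctot_b1 = ctot[b] + g.deg[i];
        const double w_ja = weight_to(g, comm, j, a) - w_ij;   // i left a
        const double w_jb2 = weight_to(g, comm, j, b) + w_ij;  // i now in b
        const double g2 = move_gain(g, j, w_jb2, w_ja, ctot_b1, ctot_a1);
        if (g1 + g2 > eps) {
          ctot[a] += g.deg[j] - g.deg[i];
          ctot[b] += g.deg[i] - g.deg[j];
          comm[i] = b;
          comm[j] = a;
          moved = true;
          any = true;
        }
      }
    }
  }
  return any;
}

// one full multilevel Louvain run followed by refinement on the original graph
std::vector<int> louvain_run(const WGraph& g0, double eps, int deep_max_n) {
  std::vector<int> memb(g0.n);
  for (int i = 0; i < g0.n; ++i) memb[i] = i;

  // multilevel phase
  WGraph g = g0;
  std::vector<int> level_map = memb;  // original node -> current supernode
  for (;;) {
    std::vector<int> comm(g.n);
    for (int i = 0; i < g.n; ++i) comm[i] = i;
    std::vector<int> ord = shuffled_order(g.n);
    local_moves(g, comm, ord, eps);
    const int C = compress(comm);
    if (C == g.n) break;
    for (int i = 0; i < g0.n; ++i) level_map[i] = comm[level_map[i]];
    // aggregate
    std::map<std::pair<int, int>, double> agg;
    for (int i = 0; i < g.n; ++i) {
      agg[std::make_pair(comm[i], comm[i])] += g.selfw[i];
      for (size_t q = 0; q < g.adj[i].size(); ++q) {
        const int j = g.adj[i][q].first;
        if (j < i) continue;
        const int a = std::min(comm[i], comm[j]), b = std::max(comm[i], comm[j]);
        agg[std::make_pair(a, b)] += (j == i) ? 0.0 : g.adj[i][q].second;
      }
    }
    std::vector<int> ei, ej;
    std::vector<double> w;
    for (std::map<std::pair<int, int>, double>::const_iterator it = agg.begin();
         it != agg.end(); ++it) {
      if (it->second == 0.0) continue;
      ei.push_back(it->first.first);
      ej.push_back(it->first.second);
      w.push_back(it->second);
    }
    WGraph gn;
    gn.build(C, ei, ej, w);
    g = gn;
  }
  memb = level_map;

  // refinement on the original graph: node sweeps and pair merges always;
  // KL chain moves and all-pairs swaps where the graph is small enough for
  // their quadratic cost
  const bool deep = g0.n <= deep_max_n;
  for (;;) {
    std::vector<int> ord = shuffled_order(g0.n);
    bool changed = local_moves(g0, memb, ord, eps);
    changed = merge_pass(g0, memb, eps) || changed;
    if (deep) {
      compress(memb);
      changed = kl_pass(g0, memb, eps) || changed;
      changed = swap_pass(g0, memb, eps) || changed;
    }
    if (!changed) break;
  }
  compress(memb);
  return memb;
}

}  // namespace

// [[Rcpp::export]]
List cpp_louvain(int n, IntegerVector ei, IntegerVector ej, NumericVector w,
                 int restarts, double eps, int deep_max_n) {
  std::vector<int> vei(ei.size()), vej(ej.size());
  std::vector<double> vw(w.size());
  for (int e = 0; e < ei.size(); ++e) {
    vei[e] = ei[e] - 1;
    vej[e] = ej[e] - 1;
    vw[e] = w[e];
  }
  WGraph g;
  g.build(n, vei, vej, vw);
  if (g.m2 <= 0.0) {
    // no edges: every node its own community
    IntegerVector lab(n);
    for (int i = 0; i < n; ++i) lab[i] = i + 1;
    return List::create(_["membership"] = lab, _["modularity"] = NA_REAL);
  }
  RNGScope scope;
  std::vector<int> best;
  double best_q = -2.0;
  for (int r = 0; r < restarts; ++r) {
    std::vector<int> memb = louvain_run(g, eps, deep_max_n);
    const int C = *std::max_element(memb.begin(), memb.end()) + 1;
    const double q = modularity_of(g, memb, C);
    if (q > best_q + eps) { best_q = q; best = memb; }
  }
  IntegerVector lab(n);
  for (int i = 0; i < n; ++i) lab[i] = best[i] + 1;
  return List::create(_["membership"] = lab, _["modularity"] = best_q);
}

// weighted Newman-Girvan modularity of a given labelling (1-based labels)
// [[Rcpp::export]]
double cpp_modularity(int n, IntegerVector ei, IntegerVector ej, NumericVector w,
                      IntegerVector labels) {
  std::vector<int> vei(ei.size()), vej(ej.size());
  std::vector<double> vw(w.size());
  for (int e = 0; e < ei.size(); ++e) {
    vei[e] = ei[e] - 1;
    vej[e] = ej[e] - 1;
    vw[e] = w[e];
  }
  WGraph g;
  g.build(n, vei, vej, vw);
  if (g.m2 <= 0.0) return NA_REAL;
  std::vector<int> comm(n);
  int C = 0;
  for (int i = 0; i < n; ++i) {
    comm[i] = labels[i] - 1;
    C = std::max(C, comm[i] + 1);
  }
  return modularity_of(g, comm, C);
}
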