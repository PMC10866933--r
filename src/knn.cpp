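#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact k-nearest neighbours within spatial groups (ROIs).
// Ties broken by (distance, lower cell index). Self excluded.
// roi: integer group code per cell. Returns 1-based global indices,
// NA-padded where a group has fewer than K other cells.
// [[Rcpp::export]]
List cpp_knn_groups(NumericVector x, NumericVector y, IntegerVector roi, int K) {
  const int n = x.size();
  IntegerMatrix idx(n, K);
  NumericMatrix dst(n, K);
  std::fill(idx.begin(), idx.end(), NA_INTEGER);
  std::fill(dst.begin(), dst.end(), NA_REAL);

  // group members
  std::vector<std::vector<int> > groups;
  {
    int gmax = 0;
    for (int i = 0; i < n; ++i) gmax = std::max(gmax, roi[i]);
    groups.resize(gmax + 1);
    for (int i = 0; i < n; ++i) groups[roi[i]].push_back(i);
  }

  std::vector<std::pair<double, int> > cand;
  for (size_t g = 0; g < groups.size(); ++g) {
    const std::vector<int>& mem = groups[g];
    const int m = (int)mem.size();
    if (m < 2) continue;
    const int keff = std::min(K, m - 1);
    for (int a = 0; a < m; ++a) {
      const int i = mem[a];
      cand.clear();
      cand.reserve(m - 1);
      for (int b = 0; b < m; ++b) {
        if (b == a) continue;
        const int j = mem[b];
        const double dx = x[i] - x[j], dy = y[i] - y[j];
        cand.push_back(std::make_pair(dx * dx + dy * dy, j));
      }
      std::partial_sort(cand.begin(), cand.begin() + keff, cand.end());
      for (int q = 0; q < keff; ++q) {
        idx(i, q) = cand[q].second + 1;
        dst(i, q) = std::sqrt(cand[q].first);
      }
    }
  }
  return List::create(_["index"] = idx, _["distance"] = dst);
}

// Exact brute-force kNN in d-dimensional feature space (rows = points).
// Same tie-break convention. Intended for moderate n.
// [[Rcpp::export]]
List cpp_knn_matrix(NumericMatrix X, int K) {
  const int n = X.nrow(), d = X.ncol();
  const int keff = std::min(K, n - 1);
  IntegerMatrix idx(n, keff);
  NumericMatrix dst(n, keff);
  std::vector<std::pair<double, int> > cand(n - 1);
  for (int i = 0; i < n; ++i) {
    int c = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double s = 0.0;
      for (int t = 0; t < d; ++t) {
        const double diff = X(i, t) - X(j, t);
        s += diff * diff;
      }
      cand[c++] = std::make_pair(s, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + keff, cand.end());
    for (int q = 0; q < keff; ++q) {
      idx(i, q) = cand[q].second + 1;
      dst(i, q) = std::sqrt(cand[q].first);
    }
  }
  return List::create(_["index"] = idx, _["distance"] = dst);
}

// Minimum Euclidean distance from each query point to a reference set.
// [[Rcpp::export]]
NumericVector cpp_min_dist(NumericVector qx, NumericVector qy,
                           NumericVector rx, NumericVector ry) {
  const int nq = qx.size(), nr = rx.size();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nr; ++j) {
      const double dx = qx[i] - rx[j], dy = qy[i] - ry[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Jaccard similarity of augmented neighbour sets ({i} union kNN(i)) for a
// list of node pairs. nn holds 1-based neighbour indices, one row per node.
// [[Rcpp::export]]
NumericVector cpp_jaccard(IntegerMatrix nn, IntegerVector ei, IntegerVector ej) {
  const int n = nn.nrow(), k = nn.ncol();
  // sorted augmented sets
  std::vector<std::vector<int> > sets(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int>& s = sets[i];
    s.reserve(k + 1);
    s.push_back(i + 1);
    for (int q = 0; q < k; ++q) {
      const int v = nn(i, q);
      if (v != NA_INTEGER) s.push_back(v);
    }
    std::sort(s.begin(), s.end());
  }
  const int ne = ei.size();
  NumericVector w(ne);
  for (int e = 0; e < ne; ++e) {
    const std::vector<int>& A = sets[ei[e] - 1];
    const std::vector<int>& B = sets[ej[e] - 1];
    size_t a = 0, b = 0;
    int inter = 0;
    while (a < A.size() && b < B.size()) {
      if (A[a] == B[b]) { ++inter; ++a; ++b; }
      else if (A[a] < B[b]) ++a;
      else ++b;
    }
    const int uni = (int)A.size() + (int)B.size() - inter;
    w[e] = uni > 0 ? (double)inter / (double)uni : 0.0;
  }
  return w;
}
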