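#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

// Squared Euclidean distance between rows i and j of a column-major matrix.
static inline double sqdist(const double *x, int n, int d, int i, int j) {
  double s = 0.0;
  for (int f = 0; f < d; ++f) {
    double diff = x[i + (size_t)f * n] - x[j + (size_t)f * n];
    s += diff * diff;
  }
  return s;
}

// Exact k nearest neighbours by brute force. Ties at the k-th neighbour are
// broken by smallest sample index; a point is never its own neighbour.
// Returns 1-based neighbour indices, each row sorted by (distance, index).
// [[Rcpp::export(name = ".knn_exact_cpp")]]
IntegerMatrix knn_exact_cpp(NumericMatrix points, int k) {
  const int n = points.nrow(), d = points.ncol();
  const double *x = points.begin();
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int>> cand(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      cand[m++] = std::make_pair(sqdist(x, n, d, i, j), j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int t = 0; t < k; ++t) out(i, t) = cand[t].second + 1;
  }
  return out;
}

namespace {

// Fixed-capacity neighbour list kept sorted ascending by (dist, idx).
struct NbrList {
  std::vector<double> dist;
  std::vector<int> idx;
  std::vector<char> isnew;
  int k;
  void init(int kk) {
    k = kk;
    dist.assign(k, std::numeric_limits<double>::infinity());
    idx.assign(k, -1);
    isnew.assign(k, 0);
  }
  // Insert candidate; returns true if the list changed.
  bool push(double d, int j) {
    if (d > dist[k - 1] || (d == dist[k - 1] && idx[k - 1] != -1 && j >= idx[k - 1]))
      return false;
    for (int t = 0; t < k; ++t)
      if (idx[t] == j) return false;
    int pos = k - 1;
    while (pos > 0 &&
           (dist[pos - 1] > d || (dist[pos - 1] == d && idx[pos - 1] > j))) {
      dist[pos] = dist[pos - 1];
      idx[pos] = idx[pos - 1];
      isnew[pos] = isnew[pos - 1];
      --pos;
    }
    dist[pos] = d;
    idx[pos] = j;
    isnew[pos] = 1;
    return true;
  }
};

inline int draw(std::mt19937 &rng, int n) {
  return (int)(rng() % (unsigned)n);
}

} // namespace

// NN-descent-style approximate k nearest neighbours (random initialisation,
// iterated local join over the new forward and reverse neighbours).
// Deterministic given `seed`; returns 1-based indices sorted by distance.
// [[Rcpp::export(name = ".knn_descent_cpp")]]
IntegerMatrix knn_descent_cpp(NumericMatrix points, int k, int seed,
                              int max_iter = 15, double delta = 0.001) {
  const int n = points.nrow(), d = points.ncol();
  const double *x = points.begin();
  std::mt19937 rng((unsigned)seed);

  std::vector<NbrList> nb(n);
  for (int i = 0; i < n; ++i) {
    nb[i].init(k);
    int filled = 0;
    while (filled < k) {
      int j = draw(rng, n);
      if (j == i) continue;
      if (nb[i].push(sqdist(x, n, d, i, j), j)) ++filled;
    }
  }

  const int max_cand = 3 * k;
  std::vector<std::vector<int>> cand(n);
  for (int iter = 0; iter < max_iter; ++iter) {
    for (int i = 0; i < n; ++i) cand[i].clear();
    // Join candidates: all forward neighbours plus the reverses of the
    // neighbours discovered in the previous round.
    for (int i = 0; i < n; ++i) {
      for (int t = 0; t < k; ++t) {
        int j = nb[i].idx[t];
        if ((int)cand[i].size() < max_cand) cand[i].push_back(j);
        if (nb[i].isnew[t]) {
          if ((int)cand[j].size() < max_cand) cand[j].push_back(i);
          nb[i].isnew[t] = 0;
        }
      }
    }
    long updates = 0;
    for (int i = 0; i < n; ++i) {
      const std::vector<int> &ci = cand[i];
      for (size_t a = 0; a < ci.size(); ++a) {
        for (size_t b = a + 1; b < ci.size(); ++b) {
          int u = ci[a], v = ci[b];
          if (u == v) continue;
          double duv = sqdist(x, n, d, u, v);
          if (nb[u].push(duv, v)) ++updates;
          if (nb[v].push(duv, u)) ++updates;
        }
      }
    }
    if (updates <= (long)(delta * (double)n * k)) break;
  }

  IntegerMatrix out(n, k);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < k; ++t) out(i, t) = nb[i].idx[t] + 1;
  return out;
}

// Shared-neighbour counts |N(i) .. N(j)| for every stored edge (i, j) of the
// kNN adjacency, by sorted-set intersection of the out-neighbour lists.
// `idx` is the n x k matrix of 1-based out-neighbour indices.
// [[Rcpp::export(name = ".snn_counts_cpp")]]
IntegerMatrix snn_counts_cpp(IntegerMatrix idx) {
  const int n = idx.nrow(), k = idx.ncol();
  std::vector<std::vector<int>> sorted(n, std::vector<int>(k));
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < k; ++t) sorted[i][t] = idx(i, t);
    std::sort(sorted[i].begin(), sorted[i].end());
  }
  IntegerMatrix counts(n, k);
  for (int i = 0; i < n; ++i) {
    const std::vector<int> &a = sorted[i];
    for (int t = 0; t < k; ++t) {
      const std::vector<int> &b = sorted[idx(i, t) - 1];
      int c = 0, p = 0, q = 0;
      while (p < k && q < k) {
        if (a[p] < b[q]) ++p;
        else if (a[p] > b[q]) ++q;
        else { ++c; ++p; ++q; }
      }
      counts(i, t) = c;
    }
  }
  return counts;
}
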