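// Leiden-style optimisation of directed, weighted modularity:
//   Q = (1/m) * sum_ab [ w_ab - gamma * kout_a * kin_b / m ] * delta(c_a, c_b)
// with m the total edge weight. Seeded queue-based local moving, a greedy
// refinement pass inside each community, and aggregation, iterated until no
// further improvement.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct DiGraph {
  int n;
  double m; // total edge weight
  std::vector<int> out_ptr, out_dst;
  std::vector<double> out_w;
  std::vector<int> in_ptr, in_src;
  std::vector<double> in_w;
  std::vector<double> self, sout, sin; // self-loop weight, strengths

  void build(int nn, const std::vector<int> &src, const std::vector<int> &dst,
             const std::vector<double> &w) {
    n = nn;
    m = 0.0;
    size_t ne = src.size();
    self.assign(n, 0.0);
    sout.assign(n, 0.0);
    sin.assign(n, 0.0);
    std::vector<int> odeg(n, 0), ideg(n, 0);
    for (size_t e = 0; e < ne; ++e) {
      m += w[e];
      sout[src[e]] += w[e];
      sin[dst[e]] += w[e];
      if (src[e] == dst[e]) self[src[e]] += w[e];
      ++odeg[src[e]];
      ++ideg[dst[e]];
    }
    out_ptr.assign(n + 1, 0);
    in_ptr.assign(n + 1, 0);
    for (int v = 0; v < n; ++v) {
      out_ptr[v + 1] = out_ptr[v] + odeg[v];
      in_ptr[v + 1] = in_ptr[v] + ideg[v];
    }
    out_dst.resize(ne);
    out_w.resize(ne);
    in_src.resize(ne);
    in_w.resize(ne);
    std::vector<int> opos(out_ptr.begin(), out_ptr.end() - 1);
    std::vector<int> ipos(in_ptr.begin(), in_ptr.end() - 1);
    for (size_t e = 0; e < ne; ++e) {
      out_dst[opos[src[e]]] = dst[e];
      out_w[opos[src[e]]++] = w[e];
      in_src[ipos[dst[e]]] = src[e];
      in_w[ipos[dst[e]]++] = w[e];
    }
  }
};

double quality(const DiGraph &g, const std::vector<int> &comm, double gamma) {
  if (g.m <= 0) return 0.0;
  double win = 0.0;
  std::vector<double> Kout(g.n, 0.0), Kin(g.n, 0.0);
  for (int v = 0; v < g.n; ++v) {
    Kout[comm[v]] += g.sout[v];
    Kin[comm[v]] += g.sin[v];
    for (int e = g.out_ptr[v]; e < g.out_ptr[v + 1]; ++e)
      if (comm[g.out_dst[e]] == comm[v]) win += g.out_w[e];
  }
  double pen = 0.0;
  for (int c = 0; c < g.n; ++c) pen += Kout[c] * Kin[c];
  return win / g.m - gamma * pen / (g.m * g.m);
}

void shuffle_order(std::vector<int> &order, std::mt19937 &rng) {
  for (int i = (int)order.size() - 1; i > 0; --i) {
    int j = (int)(rng() % (unsigned)(i + 1));
    std::swap(order[i], order[j]);
  }
}

// Queue-based local moving; `comm` is modified in place. Returns number of
// moves performed.
long local_move(const DiGraph &g, std::vector<int> &comm, double gamma,
                std::mt19937 &rng) {
  const int n = g.n;
  const double m = g.m, m2 = g.m * g.m;
  std::vector<double> Kout(n, 0.0), Kin(n, 0.0);
  std::vector<int> csize(n, 0);
  for (int v = 0; v < n; ++v) {
    Kout[comm[v]] += g.sout[v];
    Kin[comm[v]] += g.sin[v];
    ++csize[comm[v]];
  }
  std::vector<int> free_labels;
  for (int c = 0; c < n; ++c)
    if (csize[c] == 0) free_labels.push_back(c);

  std::vector<int> queue(n);
  for (int v = 0; v < n; ++v) queue[v] = v;
  shuffle_order(queue, rng);
  std::vector<char> in_queue(n, 1);
  size_t head = 0;

  std::vector<double> wto(n, 0.0);
  std::vector<int> touched;
  touched.reserve(64);
  long moves = 0;

  while (head < queue.size()) {
    int v = queue[head++];
    in_queue[v] = 0;
    // combined edge weight from/to v per neighbouring community
    touched.clear();
    for (int e = g.out_ptr[v]; e < g.out_ptr[v + 1]; ++e) {
      int u = g.out_dst[e];
      if (u == v) continue;
      int c = comm[u];
      if (wto[c] == 0.0) touched.push_back(c);
      wto[c] += g.out_w[e];
    }
    for (int e = g.in_ptr[v]; e < g.in_ptr[v + 1]; ++e) {
      int u = g.in_src[e];
      if (u == v) continue;
      int c = comm[u];
      if (wto[c] == 0.0) touched.push_back(c);
      wto[c] += g.in_w[e];
    }
    int cur = comm[v];
    Kout[cur] -= g.sout[v];
    Kin[cur] -= g.sin[v];
    --csize[cur];

    double gain_cur =
        wto[cur] / m - gamma * (g.sout[v] * Kin[cur] + g.sin[v] * Kout[cur]) / m2;
    int best = cur;
    double best_gain = gain_cur;
    for (int c : touched) {
      if (c == cur) continue;
      double gain =
          wto[c] / m - gamma * (g.sout[v] * Kin[c] + g.sin[v] * Kout[c]) / m2;
      if (gain > best_gain + 1e-12) {
        best = c;
        best_gain = gain;
      }
    }
    // option of starting a fresh singleton community
    if (best_gain < -1e-12 && csize[cur] > 0 && !free_labels.empty()) {
      best = free_labels.back();
    }

    for (int c : touched) wto[c] = 0.0;

    if (best != cur) {
      if (csize[best] == 0 && !free_labels.empty() &&
          free_labels.back() == best)
        free_labels.pop_back();
      comm[v] = best;
      ++moves;
      if (csize[cur] == 0) free_labels.push_back(cur);
      Kout[best] += g.sout[v];
      Kin[best] += g.sin[v];
      ++csize[best];
      // re-queue neighbours now outside v's new community
      for (int e = g.out_ptr[v]; e < g.out_ptr[v + 1]; ++e) {
        int u = g.out_dst[e];
        if (u != v && comm[u] != best && !in_queue[u]) {
          in_queue[u] = 1;
          queue.push_back(u);
        }
      }
      for (int e = g.in_ptr[v]; e < g.in_ptr[v + 1]; ++e) {
        int u = g.in_src[e];
        if (u != v && comm[u] != best && !in_queue[u]) {
          in_queue[u] = 1;
          queue.push_back(u);
        }
      }
    } else {
      comm[v] = cur;
      Kout[cur] += g.sout[v];
      Kin[cur] += g.sin[v];
      ++csize[cur];
    }
  }
  return moves;
}

// Greedy refinement: within each community of `comm`, singleton nodes merge
// into the best positively-gaining refined sub-community. Returns the number
// of refined communities; `rcomm` gets labels in 0..(nr-1).
int refine(const DiGraph &g, const std::vector<int> &comm,
           std::vector<int> &rcomm, double gamma, std::mt19937 &rng) {
  const int n = g.n;
  const double m = g.m, m2 = g.m * g.m;
  rcomm.resize(n);
  for (int v = 0; v < n; ++v) rcomm[v] = v;
  std::vector<double> RKout(g.sout), RKin(g.sin);
  std::vector<int> rsize(n, 1);

  std::vector<int> order(n);
  for (int v = 0; v < n; ++v) order[v] = v;
  shuffle_order(order, rng);

  std::vector<double> wto(n, 0.0);
  std::vector<int> touched;
  for (int v : order) {
    if (rsize[rcomm[v]] != 1) continue; // only singletons merge
    touched.clear();
    for (int e = g.out_ptr[v]; e < g.out_ptr[v + 1]; ++e) {
      int u = g.out_dst[e];
      if (u == v || comm[u] != comm[v]) continue;
      int c = rcomm[u];
      if (wto[c] == 0.0) touched.push_back(c);
      wto[c] += g.out_w[e];
    }
    for (int e = g.in_ptr[v]; e < g.in_ptr[v + 1]; ++e) {
      int u = g.in_src[e];
      if (u == v || comm[u] != comm[v]) continue;
      int c = rcomm[u];
      if (wto[c] == 0.0) touched.push_back(c);
      wto[c] += g.in_w[e];
    }
    int cur = rcomm[v];
    RKout[cur] -= g.sout[v];
    RKin[cur] -= g.sin[v];
    int best = cur;
    double best_gain = 0.0; // staying singleton
    for (int c : touched) {
      if (c == cur) continue;
      double gain =
          wto[c] / m - gamma * (g.sout[v] * RKin[c] + g.sin[v] * RKout[c]) / m2;
      if (gain > best_gain + 1e-12) {
        best = c;
        best_gain = gain;
      }
    }
    for (int c : touched) wto[c] = 0.0;
    rcomm[v] = best;
    RKout[best] += g.sout[v];
    RKin[best] += g.sin[v];
    if (best != cur) {
      --rsize[cur];
      ++rsize[best];
    }
  }
  // relabel to 0..(nr-1)
  std::vector<int> relab(n, -1);
  int nr = 0;
  for (int v = 0; v < n; ++v) {
    if (relab[rcomm[v]] < 0) relab[rcomm[v]] = nr++;
    rcomm[v] = relab[rcomm[v]];
  }
  return nr;
}

void aggregate(const DiGraph &g, const std::vector<int> &rcomm, int nr,
               DiGraph &agg) {
  std::vector<int> src, dst;
  std::vector<double> w;
  std::vector<double> acc(nr, 0.0);
  std::vector<int> touched;
  std::vector<std::vector<int>> members(nr);
  for (int v = 0; v < g.n; ++v) members[rcomm[v]].push_back(v);
  for (int c = 0; c < nr; ++c) {
    touched.clear();
    for (int u : members[c]) {
      for (int e = g.out_ptr[u]; e < g.out_ptr[u + 1]; ++e) {
        int t = rcomm[g.out_dst[e]];
        if (acc[t] == 0.0) touched.push_back(t);
        acc[t] += g.out_w[e];
      }
    }
    for (int t : touched) {
      src.push_back(c);
      dst.push_back(t);
      w.push_back(acc[t]);
      acc[t] = 0.0;
    }
  }
  agg.build(nr, src, dst, w);
}

} // namespace

// [[Rcpp::export(name = ".leiden_cpp")]]
List leiden_cpp(int n, IntegerVector src, IntegerVector dst, NumericVector w,
                double resolution, int seed, int max_levels = 30) {
  std::vector<int> s(src.begin(), src.end()), d(dst.begin(), dst.end());
  std::vector<double> wt(w.begin(), w.end());
  for (size_t e = 0; e < s.size(); ++e) {
    --s[e];
    --d[e];
  }
  DiGraph g;
  g.build(n, s, d, wt);

  std::vector<int> final_comm(n);
  for (int v = 0; v < n; ++v) final_comm[v] = v;
  if (g.m <= 0) {
    // no weight anywhere: a single community (quality 0) is the optimum
    std::fill(final_comm.begin(), final_comm.end(), 0);
    return List::create(_["membership"] = wrap(final_comm),
                        _["quality"] = 0.0);
  }

  std::mt19937 rng((unsigned)seed);
  std::vector<int> node_map(n);
  for (int v = 0; v < n; ++v) node_map[v] = v;

  DiGraph cur = g;
  std::vector<int> comm(cur.n);
  for (int v = 0; v < cur.n; ++v) comm[v] = v;

  for (int level = 0; level < max_levels; ++level) {
    long moves = local_move(cur, comm, resolution, rng);
    // count communities
    std::vector<int> relab(cur.n, -1);
    int nc = 0;
    for (int v = 0; v < cur.n; ++v)
      if (relab[comm[v]] < 0) relab[comm[v]] = nc++;
    if (nc == cur.n || (level > 0 && moves == 0)) {
      for (int v = 0; v < cur.n; ++v) comm[v] = relab[comm[v]];
      break;
    }
    std::vector<int> rcomm;
    int nr = refine(cur, comm, rcomm, resolution, rng);
    if (nr == cur.n && moves == 0) break;
    // aggregate on the refined partition; aggregate nodes inherit the
    // local-moving community of their members
    DiGraph agg;
    aggregate(cur, rcomm, nr, agg);
    std::vector<int> agg_comm(nr);
    for (int v = 0; v < cur.n; ++v) agg_comm[rcomm[v]] = relab[comm[v]];
    for (int i = 0; i < n; ++i) node_map[i] = rcomm[node_map[i]];
    cur = agg;
    comm = agg_comm;
  }

  for (int i = 0; i < n; ++i) final_comm[i] = comm[node_map[i]];
  // canonical labels by first appearance
  std::vector<int> relab(n, -1);
  int nc = 0;
  for (int i = 0; i < n; ++i) {
    if (relab[final_comm[i]] < 0) relab[final_comm[i]] = nc++;
    final_comm[i] = relab[final_comm[i]];
  }
  double q = quality(g, final_comm, resolution);
  // never return a partition worse than the trivial all-in-one baseline
  double q_one = 1.0 - resolution;
  if (q < q_one) {
    std::fill(final_comm.begin(), final_comm.end(), 0);
    q = q_one;
  }
  return List::create(_["membership"] = wrap(final_comm), _["quality"] = q);
}
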