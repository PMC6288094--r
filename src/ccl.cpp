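#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving.
static inline int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static inline void uf_union(std::vector<int> &parent, std::vector<int> &rank_,
                            int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a == b) return;
  if (rank_[a] < rank_[b]) std::swap(a, b);
  parent[b] = a;
  if (rank_[a] == rank_[b]) rank_[a]++;
}

// Label 8-connected (Moore neighbourhood) components of a binary grid.
// Returns an integer matrix: 0 for background, 1..K component labels in
// first-encounter (row-major) order. `periodic` wraps both axes.
// [[Rcpp::export(name = ".ccl_label")]]
IntegerMatrix ccl_label(const LogicalMatrix &mask, bool periodic = false) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const R_xlen_t n = (R_xlen_t)nr * nc;
  std::vector<int> parent(n), rank_(n, 0);
  for (R_xlen_t i = 0; i < n; ++i) parent[i] = (int)i;

  // Column-major indexing: idx = r + c*nr. For each forest cell, union with
  // the 4 already-visited Moore neighbours (W, NW, N, NE in column-major
  // sweep terms); with periodic boundaries also the wrapped ones.
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      const int idx = r + c * nr;
      // neighbour offsets covering half the Moore stencil
      const int dr[4] = {-1, -1, -1, 0};
      const int dc[4] = {-1, 0, 1, -1};
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (periodic) {
          rr = (rr + nr) % nr;
          cc = (cc + nc) % nc;
        } else if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) {
          continue;
        }
        if (mask(rr, cc)) uf_union(parent, rank_, idx, rr + cc * nr);
      }
    }
  }

  IntegerMatrix out(nr, nc);
  std::vector<int> relabel(n, 0);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int root = uf_find(parent, r + c * nr);
      if (relabel[root] == 0) relabel[root] = ++next;
      out(r, c) = relabel[root];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Hartigan's dip statistic.
//
// dip(F_n) = min_G sup_x |F_n(x) - G(x)| over unimodal distribution
// functions G (convex then concave, an atom allowed at the mode). For a
// candidate half-width d the one-sided feasibility is checked by a greedy
// minimal convex trajectory through the bands
//   a_i = F_i - d  <=  G(t_i)  <=  b_i = F_{i-1} + d
// at the distinct sorted values t_i (the b_i bound comes from the left limit
// of the ECDF at a jump). The concave side is the mirror image. The dip is
// found by bisection on d; the mode may sit in any gap between data points.

// Largest prefix length m (0..k) such that a convex nondecreasing function
// can pass through the bands [a_i, b_i] at positions t_i for all i < m.
// A convex function g with g(t_i) <= b_i lies below every chord of the
// b-points, hence below their lower convex hull; conversely the hull itself
// is a feasible convex path. So the prefix is feasible iff the lower convex
// hull of the b-points dominates the a-points. The hull is grown
// incrementally with a vertex stack; after each insertion only the final
// hull segment needs re-checking against a.
static size_t convex_prefix(const std::vector<double> &t,
                            const std::vector<double> &a,
                            const std::vector<double> &b) {
  const size_t k = t.size();
  const double tol = 1e-12;
  std::vector<size_t> hull; // indices of hull vertices
  hull.reserve(k);
  for (size_t j = 0; j < k; ++j) {
    if (a[j] > b[j] + tol) return j;
    while (hull.size() >= 2) {
      size_t p = hull[hull.size() - 2], q = hull.back();
      double s1 = (b[q] - b[p]) / (t[q] - t[p]);
      double s2 = (b[j] - b[q]) / (t[j] - t[q]);
      if (s1 >= s2) hull.pop_back(); else break;
    }
    if (!hull.empty()) {
      size_t v = hull.back();
      double slope = (b[j] - b[v]) / (t[j] - t[v]);
      for (size_t i = v + 1; i < j; ++i) {
        double hv = b[v] + slope * (t[i] - t[v]);
        if (hv + tol < a[i]) return j;
      }
    }
    hull.push_back(j);
  }
  return k;
}

static bool dip_feasible(const std::vector<double> &t,
                         const std::vector<double> &F, double d) {
  const size_t k = t.size();
  std::vector<double> a(k), b(k);
  for (size_t i = 0; i < k; ++i) {
    a[i] = std::max(F[i] - d, 0.0);
    b[i] = std::min((i == 0 ? 0.0 : F[i - 1]) + d, 1.0);
  }
  // left (convex) side: largest feasible prefix
  size_t jmax = convex_prefix(t, a, b);
  // right (concave) side via the mirror x -> -x, G -> 1 - G, which maps it
  // onto a convex side with bands [1 - b, 1 - a]
  std::vector<double> tm(k), am(k), bm(k);
  for (size_t i = 0; i < k; ++i) {
    tm[i] = -t[k - 1 - i];
    am[i] = 1.0 - b[k - 1 - i];
    bm[i] = 1.0 - a[k - 1 - i];
  }
  size_t suf = convex_prefix(tm, am, bm); // feasible suffix length
  // The mode sits at a shared data point: the convex branch covers points
  // 1..j and the concave branch j..k, overlapping at j. The shared point
  // transmits the slope ordering across the peak (at the mode the slope may
  // only drop), so feasibility needs the branches to cover k + 1 point
  // slots between them.
  return jmax + suf >= k + 1;
}

// [[Rcpp::export(name = ".dip_stat")]]
double dip_stat(const NumericVector &x) {
  const R_xlen_t n = x.size();
  if (n < 2) return 0.0;
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  // collapse ties into distinct values with ECDF heights
  std::vector<double> t, F;
  t.reserve(n);
  F.reserve(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!t.empty() && xs[i] == t.back()) {
      F.back() = (double)(i + 1) / n;
    } else {
      t.push_back(xs[i]);
      F.push_back((double)(i + 1) / n);
    }
  }
  if (t.size() == 1) return 0.0;
  double lo = 0.0, hi = 0.25; // dip never exceeds 1/4
  if (dip_feasible(t, F, lo)) return 0.0;
  for (int it = 0; it < 60; ++it) {
    double mid = 0.5 * (lo + hi);
    if (dip_feasible(t, F, mid)) hi = mid; else lo = mid;
  }
  return 0.5 * (lo + hi);
}

// Monte-Carlo dip null distribution for sample size n (uniform null).
// Uses R's RNG so results follow set.seed().
// [[Rcpp::export(name = ".dip_null")]]
NumericVector dip_null(int n, int reps) {
  NumericVector out(reps);
  NumericVector u(n);
  for (int r = 0; r < reps; ++r) {
    for (int i = 0; i < n; ++i) u[i] = unif_rand();
    out[r] = dip_stat(u);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Contact process: asynchronous single-site updates on an LxL grid, Moore
// neighbourhood, extinction rate normalised to 1, colonisation rate lambda
// per fully-occupied neighbourhood. One sweep = L*L update attempts.
// Occupied site empties with prob 1/(1+lambda); empty site fills with prob
// (lambda/(1+lambda)) * k/8 where k = occupied Moore neighbours.
// [[Rcpp::export(name = ".contact_process_run")]]
LogicalVector contact_process_run(LogicalVector state, int L, int sweeps,
                                  double lambda, bool periodic = true,
                                  int record_every = 1) {
  // state modified in place per sweep; snapshots appended when
  // (sweep % record_every) == 0. Returns concatenated snapshots.
  std::vector<char> occ(state.begin(), state.end());
  const double p_die = 1.0 / (1.0 + lambda);
  const double p_col = lambda / (1.0 + lambda);
  std::vector<char> snaps;
  snaps.reserve((size_t)L * L * (sweeps / record_every + 1));
  const long long attempts = (long long)L * L;
  for (int s = 1; s <= sweeps; ++s) {
    for (long long aidx = 0; aidx < attempts; ++aidx) {
      int idx = (int)(unif_rand() * L * L);
      if (idx >= L * L) idx = L * L - 1;
      int r = idx % L, c = idx / L;
      if (occ[idx]) {
        if (unif_rand() < p_die) occ[idx] = 0;
      } else {
        int k = 0;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int rr = r + dr, cc = c + dc;
            if (periodic) {
              rr = (rr + L) % L;
              cc = (cc + L) % L;
            } else if (rr < 0 || rr >= L || cc < 0 || cc >= L) {
              continue;
            }
            if (occ[rr + cc * L]) ++k;
          }
        }
        if (k > 0 && unif_rand() < p_col * k / 8.0) occ[idx] = 1;
      }
    }
    if (s % record_every == 0) {
      snaps.insert(snaps.end(), occ.begin(), occ.end());
    }
  }
  LogicalVector out(snaps.size());
  for (size_t i = 0; i < snaps.size(); ++i) out[i] = snaps[i] != 0;
  return out;
}
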