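#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sup-norm distance between two bivariate empirical copulas.
//
// The difference D(u,v) = C_A(u,v) - C_B(u,v) of two empirical-CDF-like step
// functions is piecewise constant and right-continuous, so its supremum over
// (0,1)^2 is attained on the product grid {pooled u values} x {pooled v
// values}.  The exact evaluator sweeps the pooled u values in increasing
// order; a bottom-up segment tree over v-ranks maintains, under point
// inserts of +-1/n weights, the maximum and minimum prefix sum — i.e. the
// extrema of D over all v thresholds at the current u.  One evaluation costs
// O(n log n).
//
// The permutation test exploits that permuting each marginal within each
// sample only re-pairs u-slots with v-ranks: the sorted u sweep order, the
// tie batches and the per-sample v-rank multisets are all invariant, so a
// permutation is just a shuffle of two small integer arrays and a fresh
// sweep — no sorting inside the permutation loop.

struct PrefTree {
  int size = 0;                       // power of two >= number of v ranks
  std::vector<double> sum, mx, mn;    // 2*size nodes, children of i at 2i,2i+1

  void init(int r) {
    size = 1;
    while (size < r) size <<= 1;
    sum.assign(2 * size, 0.0);
    mx.assign(2 * size, 0.0);
    mn.assign(2 * size, 0.0);
  }
  void reset() {
    std::fill(sum.begin(), sum.end(), 0.0);
    std::fill(mx.begin(), mx.end(), 0.0);
    std::fill(mn.begin(), mn.end(), 0.0);
  }
  inline void add(int r, double w) {
    int i = r + size;
    sum[i] += w; mx[i] = sum[i]; mn[i] = sum[i];
    for (i >>= 1; i >= 1; i >>= 1) {
      int l = 2 * i, rr = 2 * i + 1;
      sum[i] = sum[l] + sum[rr];
      mx[i] = std::max(mx[l], sum[l] + mx[rr]);
      mn[i] = std::min(mn[l], sum[l] + mn[rr]);
    }
  }
  inline double best_abs() const { return std::max(mx[1], -mn[1]); }
};

struct EcopExact {
  int n = 0, nA = 0, nB = 0, R = 0;
  double wA = 0, wB = 0;
  std::vector<int> slot_sample;   // sample of each sorted-u slot (0 = A)
  std::vector<char> batch_end;    // slot closes a group of tied u values
  std::vector<int> vr_sorted;     // observed pairing: v-rank per sorted slot
  std::vector<int> vrA, vrB;      // per-sample v-rank multisets (shuffled)
  PrefTree tree;

  void setup(const double* uA, const double* vA, int nA_,
             const double* uB, const double* vB, int nB_) {
    nA = nA_; nB = nB_; n = nA + nB;
    wA = 1.0 / nA; wB = -1.0 / nB;
    std::vector<double> u(n), v(n);
    for (int i = 0; i < nA; ++i) { u[i] = uA[i]; v[i] = vA[i]; }
    for (int i = 0; i < nB; ++i) { u[nA + i] = uB[i]; v[nA + i] = vB[i]; }

    std::vector<double> vs(v);
    std::sort(vs.begin(), vs.end());
    vs.erase(std::unique(vs.begin(), vs.end()), vs.end());
    R = (int)vs.size();
    std::vector<int> vr(n);
    for (int i = 0; i < n; ++i)
      vr[i] = (int)(std::lower_bound(vs.begin(), vs.end(), v[i]) - vs.begin());

    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return u[a] < u[b]; });

    slot_sample.resize(n); batch_end.resize(n); vr_sorted.resize(n);
    vrA.clear(); vrB.clear();
    for (int s = 0; s < n; ++s) {
      int id = ord[s];
      slot_sample[s] = id < nA ? 0 : 1;
      vr_sorted[s] = vr[id];
      if (id < nA) vrA.push_back(vr[id]); else vrB.push_back(vr[id]);
      batch_end[s] = (s == n - 1) || (u[ord[s + 1]] != u[id]);
    }
    tree.init(R);
  }

  // sweep with the observed pairing (permuted = false) or with the current
  // contents of vrA/vrB assigned in order to each sample's slots
  double sweep(bool permuted) {
    tree.reset();
    double best = 0.0;
    int ia = 0, ib = 0;
    for (int s = 0; s < n; ++s) {
      int r;
      double w;
      if (slot_sample[s] == 0) {
        r = permuted ? vrA[ia++] : vr_sorted[s];
        w = wA;
      } else {
        r = permuted ? vrB[ib++] : vr_sorted[s];
        w = wB;
      }
      tree.add(r, w);
      if (batch_end[s]) {
        double b = tree.best_abs();
        if (b > best) best = b;
      }
    }
    return best;
  }
};

template <typename T>
static inline void shuffle_inplace(std::vector<T>& x) {
  for (int i = (int)x.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(x[i], x[j]);
  }
}

// Evaluation on an m x m regular lattice over (0,1]^2: bin, 2-D cumulative
// sum, track the maximal absolute difference.  Used when n is large.
static double dist_grid(const double* uA, const double* vA, int nA,
                        const double* uB, const double* vB, int nB,
                        int m, std::vector<double>& grid) {
  grid.assign((size_t)m * m, 0.0);
  const double wA = 1.0 / nA, wB = -1.0 / nB;
  auto bin = [m](double x) {
    int b = (int)std::ceil(x * m) - 1;
    if (b < 0) b = 0;
    if (b >= m) b = m - 1;
    return b;
  };
  for (int i = 0; i < nA; ++i) grid[(size_t)bin(uA[i]) * m + bin(vA[i])] += wA;
  for (int i = 0; i < nB; ++i) grid[(size_t)bin(uB[i]) * m + bin(vB[i])] += wB;
  double best = 0.0;
  for (int i = 0; i < m; ++i) {
    double* row = &grid[(size_t)i * m];
    const double* prev = i > 0 ? &grid[(size_t)(i - 1) * m] : nullptr;
    double rowsum = 0.0;
    for (int j = 0; j < m; ++j) {
      rowsum += row[j];
      row[j] = rowsum + (prev ? prev[j] : 0.0);
      double a = std::fabs(row[j]);
      if (a > best) best = a;
    }
  }
  return best;
}

//' @noRd
// [[Rcpp::export(name = ".ecop_dist_cpp")]]
double ecop_dist_cpp(NumericVector ua, NumericVector va,
                     NumericVector ub, NumericVector vb, int grid_m) {
  if (grid_m > 0) {
    std::vector<double> grid;
    return dist_grid(ua.begin(), va.begin(), ua.size(),
                     ub.begin(), vb.begin(), ub.size(), grid_m, grid);
  }
  EcopExact e;
  e.setup(ua.begin(), va.begin(), ua.size(), ub.begin(), vb.begin(), ub.size());
  return e.sweep(false);
}

//' @noRd
// [[Rcpp::export(name = ".ecop_perm_cpp")]]
List ecop_perm_cpp(NumericVector ua, NumericVector va,
                   NumericVector ub, NumericVector vb,
                   int nperm, int grid_m, bool return_null) {
  RNGScope scope;
  const int nA = ua.size(), nB = ub.size();
  NumericVector nulld(return_null ? nperm : 0);
  double d_obs;
  int n_greater = 0;

  if (grid_m > 0) {
    std::vector<double> grid;
    d_obs = dist_grid(ua.begin(), va.begin(), nA, ub.begin(), vb.begin(), nB,
                      grid_m, grid);
    std::vector<double> pua(ua.begin(), ua.end()), pva(va.begin(), va.end());
    std::vector<double> pub(ub.begin(), ub.end()), pvb(vb.begin(), vb.end());
    for (int t = 0; t < nperm; ++t) {
      shuffle_inplace(pua); shuffle_inplace(pva);
      shuffle_inplace(pub); shuffle_inplace(pvb);
      double d = dist_grid(pua.data(), pva.data(), nA,
                           pub.data(), pvb.data(), nB, grid_m, grid);
      if (d > d_obs) ++n_greater;       // simi' < simi  <=>  d' > d_obs
      if (return_null) nulld[t] = d;
    }
  } else {
    EcopExact e;
    e.setup(ua.begin(), va.begin(), nA, ub.begin(), vb.begin(), nB);
    d_obs = e.sweep(false);
    for (int t = 0; t < nperm; ++t) {
      // independently permuting each marginal within a sample re-pairs the
      // u-slots with a uniformly random assignment of the sample's v-ranks
      shuffle_inplace(e.vrA);
      shuffle_inplace(e.vrB);
      double d = e.sweep(true);
      if (d > d_obs) ++n_greater;
      if (return_null) nulld[t] = d;
    }
  }
  List out = List::create(_["dist"] = d_obs, _["n_greater"] = n_greater);
  if (return_null) out["null"] = nulld;
  return out;
}
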