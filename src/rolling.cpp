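#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fenwick (binary indexed) tree over value ranks: supports add/remove of one
// occurrence and k-th order-statistic queries in O(log m). Used for sliding
// window quantiles so a month-long window stays O(n log n) overall.
struct Fenwick {
  std::vector<int> t;
  int n;
  Fenwick(int n_) : t(n_ + 1, 0), n(n_) {}
  void add(int i, int v) { for (++i; i <= n; i += i & -i) t[i] += v; }
  // 0-based index of the k-th (1-based) smallest stored rank
  int kth(int k) const {
    int pos = 0, rem = k;
    for (int pw = 1 << 30; pw; pw >>= 1)
      if (pos + pw <= n && t[pos + pw] < rem) { pos += pw; rem -= t[pos]; }
    return pos;  // 0-based rank
  }
};

// Centered rolling quantile with NA skipping and window shrink at the record
// ends. Window of length w covers [i - floor(w/2), i + w - 1 - floor(w/2)]
// clamped to the record; quantile uses linear interpolation of order
// statistics (R's default type 7).
// [[Rcpp::export]]
NumericVector cpp_roll_quantile(NumericVector x, int window, double prob) {
  int n = x.size();
  if (window < 1) stop("window must be >= 1");
  if (prob < 0 || prob > 1) stop("prob must be in [0, 1]");
  NumericVector out(n);

  // coordinate-compress finite values
  std::vector<double> vals;
  vals.reserve(n);
  for (int i = 0; i < n; ++i)
    if (R_finite(x[i])) vals.push_back(x[i]);
  std::sort(vals.begin(), vals.end());
  vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
  int m = vals.size();
  if (m == 0) { std::fill(out.begin(), out.end(), NA_REAL); return out; }

  std::vector<int> rank(n, -1);
  for (int i = 0; i < n; ++i)
    if (R_finite(x[i]))
      rank[i] = std::lower_bound(vals.begin(), vals.end(), x[i]) - vals.begin();

  Fenwick fw(m);
  int left = window / 2;               // samples before i
  int lo = 0, hi = -1, cnt = 0;        // current window [lo, hi], cnt finite
  for (int i = 0; i < n; ++i) {
    int tlo = std::max(0, i - left);
    int thi = std::min(n - 1, i - left + window - 1);
    while (hi < thi) { ++hi; if (rank[hi] >= 0) { fw.add(rank[hi], 1); ++cnt; } }
    while (lo < tlo) { if (rank[lo] >= 0) { fw.add(rank[lo], -1); --cnt; } ++lo; }
    if (cnt == 0) { out[i] = NA_REAL; continue; }
    double h = (cnt - 1) * prob;
    int j = (int)std::floor(h);
    double g = h - j;
    double vj = vals[fw.kth(j + 1)];
    if (g <= 0 || j + 1 >= cnt) { out[i] = vj; continue; }
    double vj1 = vals[fw.kth(j + 2)];
    out[i] = vj + g * (vj1 - vj);
  }
  return out;
}

// Centered rolling mean, same window convention and NA handling as above.
// [[Rcpp::export]]
NumericVector cpp_roll_mean(NumericVector x, int window) {
  int n = x.size();
  if (window < 1) stop("window must be >= 1");
  std::vector<double> csum(n + 1, 0.0);
  std::vector<int> ccnt(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    bool ok = R_finite(x[i]);
    csum[i + 1] = csum[i] + (ok ? x[i] : 0.0);
    ccnt[i + 1] = ccnt[i] + (ok ? 1 : 0);
  }
  int left = window / 2;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - left);
    int hi = std::min(n - 1, i - left + window - 1);
    int cnt = ccnt[hi + 1] - ccnt[lo];
    out[i] = cnt > 0 ? (csum[hi + 1] - csum[lo]) / cnt : NA_REAL;
  }
  return out;
}

// One forward pass of the Lyne-Hollick recursive digital filter.
// Quickflow recursion qf[i] = alpha * qf[i-1] + (1+alpha)/2 * (q[i]-q[i-1]),
// with qf clipped to [0, q[i]] at every step (the clipped value is carried
// forward), so 0 <= baseflow <= q holds exactly. Returns the baseflow.
// [[Rcpp::export]]
NumericVector cpp_lh_pass(NumericVector q, double alpha) {
  int n = q.size();
  NumericVector bf(n);
  if (n == 0) return bf;
  double qf = 0.0;
  bf[0] = q[0];
  for (int i = 1; i < n; ++i) {
    double f = alpha * qf + 0.5 * (1.0 + alpha) * (q[i] - q[i - 1]);
    if (f < 0.0) f = 0.0;
    if (f > q[i]) f = q[i];
    qf = f;
    bf[i] = q[i] - qf;
  }
  return bf;
}
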