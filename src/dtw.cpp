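#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// Dynamic-programming core for dynamic time warping with an optional
// Sakoe-Chiba band (|i - j| <= band on 0-based indices). Local cost is the
// absolute difference; the path cost is the unnormalized sum along the path
// with the symmetric step set {(1,0),(0,1),(1,1)}, unit weights.

static inline double local_cost(double x, double y) { return std::fabs(x - y); }

// Distance-only DP with two rolling rows: used for best-matching-unit search.
// band < 0 means unconstrained. Caller guarantees band >= |n - m| when given.
// [[Rcpp::export(name = ".dtw_dist_cpp")]]
double dtw_dist_cpp(NumericVector a, NumericVector b, int band) {
  const int n = a.size(), m = b.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m, INF), cur(m, INF);
  for (int i = 0; i < n; ++i) {
    int jlo = 0, jhi = m - 1;
    if (band >= 0) {
      jlo = std::max(0, i - band);
      jhi = std::min(m - 1, i + band);
    }
    std::fill(cur.begin(), cur.end(), INF);
    for (int j = jlo; j <= jhi; ++j) {
      double d = local_cost(a[i], b[j]);
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else {
        best = INF;
        if (i > 0) best = std::min(best, prev[j]);            // (1,0)
        if (j > 0) best = std::min(best, cur[j - 1]);         // (0,1)
        if (i > 0 && j > 0) best = std::min(best, prev[j - 1]); // (1,1)
      }
      cur[j] = d + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Full DP with backtracking. Tie-break while backtracking: prefer the
// diagonal predecessor, then (i-1, j), then (i, j-1) — deterministic because
// optimal paths are not unique. Returns 1-based index pairs in path order.
// [[Rcpp::export(name = ".dtw_path_cpp")]]
List dtw_path_cpp(NumericVector a, NumericVector b, int band) {
  const int n = a.size(), m = b.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> D((size_t)n * m, INF);
  auto at = [&](int i, int j) -> double& { return D[(size_t)i * m + j]; };

  for (int i = 0; i < n; ++i) {
    int jlo = 0, jhi = m - 1;
    if (band >= 0) {
      jlo = std::max(0, i - band);
      jhi = std::min(m - 1, i + band);
    }
    for (int j = jlo; j <= jhi; ++j) {
      double d = local_cost(a[i], b[j]);
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else {
        best = INF;
        if (i > 0) best = std::min(best, at(i - 1, j));
        if (j > 0) best = std::min(best, at(i, j - 1));
        if (i > 0 && j > 0) best = std::min(best, at(i - 1, j - 1));
      }
      at(i, j) = d + best;
    }
  }

  double dist = at(n - 1, m - 1);

  // Backtrack from the bottom-right corner.
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i); pj.push_back(j);
  while (i > 0 || j > 0) {
    double diag = (i > 0 && j > 0) ? at(i - 1, j - 1) : INF;
    double up   = (i > 0) ? at(i - 1, j) : INF;
    double left = (j > 0) ? at(i, j - 1) : INF;
    double best = std::min(diag, std::min(up, left));
    if (diag == best) { --i; --j; }
    else if (up == best) { --i; }
    else { --j; }
    pi.push_back(i); pj.push_back(j);
  }

  const int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k] + 1;  // 1-based, path order
    path(k, 1) = pj[L - 1 - k] + 1;
  }
  return List::create(_["distance"] = dist, _["path"] = path);
}
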