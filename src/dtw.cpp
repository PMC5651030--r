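#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Dynamic Time Warping between equal-length series under a Sakoe-Chiba band.
// Step set {(1,0),(0,1),(1,1)}; accumulated (unnormalized) optimal cost.
// Path length is recovered by backtracking one optimal path, preferring the
// diagonal predecessor on cost ties so the reported length is deterministic
// and minimal among ties in the common cases.
// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericVector x, NumericVector y, int radius, bool squared) {
  const int t = x.size();
  if (y.size() != t) stop("series must have equal length");
  if (t < 1) stop("empty series");
  if (radius < 0) stop("radius must be non-negative");

  const double inf = std::numeric_limits<double>::infinity();
  // D is (t+1) x (t+1), row-major; D[0][0] = 0, first row/col infinite.
  std::vector<double> d((t + 1) * (t + 1), inf);
  d[0] = 0.0;
  for (int i = 1; i <= t; ++i) {
    const int jlo = std::max(1, i - radius);
    const int jhi = std::min(t, i + radius);
    for (int j = jlo; j <= jhi; ++j) {
      double c = x[i - 1] - y[j - 1];
      c = squared ? c * c : std::fabs(c);
      const double diag = d[(i - 1) * (t + 1) + (j - 1)];
      const double up   = d[(i - 1) * (t + 1) + j];
      const double left = d[i * (t + 1) + (j - 1)];
      double best = diag;
      if (up < best) best = up;
      if (left < best) best = left;
      d[i * (t + 1) + j] = c + best;
    }
  }
  const double dist = d[t * (t + 1) + t];
  if (!R_FINITE(dist)) stop("no warping path inside the band");

  // Backtrack one optimal path; diagonal wins ties, then up, then left.
  int i = t, j = t, len = 1;
  while (i > 1 || j > 1) {
    const double diag = d[(i - 1) * (t + 1) + (j - 1)];
    const double up   = d[(i - 1) * (t + 1) + j];
    const double left = d[i * (t + 1) + (j - 1)];
    if (diag <= up && diag <= left) {
      --i; --j;
    } else if (up <= left) {
      --i;
    } else {
      --j;
    }
    ++len;
  }
  return List::create(_["distance"] = dist, _["path_length"] = len);
}

// All-pairs DTW over the columns of a T x N signal matrix; returns the
// accumulated-cost matrix and the raw path-length matrix (diagonal T).
// [[Rcpp::export(name = ".dtw_all_pairs")]]
List dtw_all_pairs(NumericMatrix signals, int radius, bool squared) {
  const int t = signals.nrow();
  const int n = signals.ncol();
  NumericMatrix dist(n, n), plen(n, n);
  for (int a = 0; a < n; ++a) {
    plen(a, a) = t;
    for (int b = a + 1; b < n; ++b) {
      List r = dtw_core(signals(_, a), signals(_, b), radius, squared);
      const double dd = r["distance"];
      const int ll = r["path_length"];
      dist(a, b) = dist(b, a) = dd;
      plen(a, b) = plen(b, a) = ll;
    }
  }
  return List::create(_["distance"] = dist, _["path_length"] = plen);
}
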