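#include <Rcpp.h>
using namespace Rcpp;

// Directed Hausdorff distance h(A,B) = max_a min_b ||a - b|| between two
// 2-D point sets (use y = 0 for 1-D sets).  Early abort: the inner scan over
// B stops as soon as a point closer than the current running maximum is
// found, which makes the typical cost far below the O(nm) worst case.
// [[Rcpp::export]]
double directed_hausdorff_cpp(NumericVector ax, NumericVector ay,
                              NumericVector bx, NumericVector by) {
  const int n = ax.size(), m = bx.size();
  double cmax = 0.0;
  for (int i = 0; i < n; ++i) {
    double dmin = R_PosInf;
    const double x = ax[i], y = ay[i];
    for (int j = 0; j < m; ++j) {
      const double dx = x - bx[j], dy = y - by[j];
      const double d = dx * dx + dy * dy;
      if (d < dmin) {
        dmin = d;
        if (dmin <= cmax) break;  // cannot raise the running max
      }
    }
    if (dmin > cmax) cmax = dmin;
  }
  return std::sqrt(cmax);
}

// Template match counts shared by sample entropy and approximate entropy.
// Returns, for embedding dimensions m and m+1, the number of template pairs
// (i, j), i != j, whose Chebyshev distance is <= r.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nm = n - m;  // number of m+1-length templates is nm; m-length is n-m+1
  double a = 0.0, b = 0.0;
  // iterate over pairs of m-length templates starting at i, j (0-based),
  // i < j <= n - m - 1 ensures the (m+1)-th element exists for the A count
  for (int i = 0; i < nm; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        const double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) break;
      }
      if (d <= r) {
        b += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) a += 1.0;
      }
    }
  }
  return NumericVector::create(a, b);
}

// phi_m(r) for approximate entropy: mean over i of log(C_i^m(r)), where
// C_i^m(r) counts templates j (including j = i) within Chebyshev radius r.
// [[Rcpp::export]]
double apen_phi_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m + 1;
  double acc = 0.0;
  for (int i = 0; i < nt; ++i) {
    int cnt = 0;
    for (int j = 0; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        const double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) break;
      }
      if (d <= r) ++cnt;
    }
    acc += std::log((double)cnt / (double)nt);
  }
  return acc / (double)nt;
}
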