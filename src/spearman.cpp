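#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Pairwise-complete Spearman correlations with average ranks for ties.
// Returns the p x p correlation matrix (NA where undefined) and the
// matrix of complete-pair counts.

static void avg_ranks(const std::vector<double> &v,
                      std::vector<double> &r,
                      std::vector<int> &ord) {
  int n = v.size();
  ord.resize(n);
  r.resize(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && v[ord[j + 1]] == v[ord[i]]) ++j;
    double rank = 0.5 * (i + j) + 1.0;  // average rank, 1-based
    for (int k = i; k <= j; ++k) r[ord[k]] = rank;
    i = j + 1;
  }
}

// [[Rcpp::export]]
List spearman_pairwise(NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix rho(p, p);
  IntegerMatrix cnt(p, p);
  std::vector<double> xi, yj, rx, ry;
  std::vector<int> ord;
  xi.reserve(n); yj.reserve(n);

  for (int i = 0; i < p; ++i) {
    rho(i, i) = 1.0;
    int ni = 0;
    for (int r = 0; r < n; ++r)
      if (!NumericMatrix::is_na(X(r, i))) ++ni;
    cnt(i, i) = ni;
    for (int j = i + 1; j < p; ++j) {
      xi.clear(); yj.clear();
      for (int r = 0; r < n; ++r) {
        double a = X(r, i), b = X(r, j);
        if (!NumericMatrix::is_na(a) && !NumericMatrix::is_na(b)) {
          xi.push_back(a);
          yj.push_back(b);
        }
      }
      int m = xi.size();
      cnt(i, j) = cnt(j, i) = m;
      if (m < 2) {
        rho(i, j) = rho(j, i) = NA_REAL;
        continue;
      }
      avg_ranks(xi, rx, ord);
      avg_ranks(yj, ry, ord);
      double mx = 0, my = 0;
      for (int k = 0; k < m; ++k) { mx += rx[k]; my += ry[k]; }
      mx /= m; my /= m;
      double sxy = 0, sxx = 0, syy = 0;
      for (int k = 0; k < m; ++k) {
        double dx = rx[k] - mx, dy = ry[k] - my;
        sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
      }
      if (sxx <= 0 || syy <= 0) {
        rho(i, j) = rho(j, i) = NA_REAL;
      } else {
        rho(i, j) = rho(j, i) = sxy / std::sqrt(sxx * syy);
      }
    }
  }
  return List::create(_["rho"] = rho, _["n"] = cnt);
}
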