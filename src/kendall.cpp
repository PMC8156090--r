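#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Tie-corrected Kendall tau-b with the normal approximation on S = C - D.
// tau_b = S / sqrt((n0 - n1)(n0 - n2)), n0 = n(n-1)/2,
// n1 = sum_t t(t-1)/2 over tie groups of x, n2 likewise for y.
// var(S) uses the standard three-term tie-corrected expression.

namespace {

struct TieSums {
  long double s1;  // sum t(t-1)/2
  long double s2;  // sum t(t-1)(2t+5)
  long double s3;  // sum t(t-1)
  long double s4;  // sum t(t-1)(t-2)
};

TieSums tie_sums(std::vector<double> v) {
  std::sort(v.begin(), v.end());
  TieSums ts = {0.0L, 0.0L, 0.0L, 0.0L};
  size_t i = 0;
  while (i < v.size()) {
    size_t j = i;
    while (j < v.size() && v[j] == v[i]) ++j;
    long double t = (long double)(j - i);
    ts.s1 += t * (t - 1) / 2;
    ts.s2 += t * (t - 1) * (2 * t + 5);
    ts.s3 += t * (t - 1);
    ts.s4 += t * (t - 1) * (t - 2);
    i = j;
  }
  return ts;
}

// core: fills tau, z, p; returns false when tau is undefined
bool tau_core(const std::vector<double>& x, const std::vector<double>& y,
              double& tau, double& z, double& p) {
  const int n = (int)x.size();
  if (n < 3) return false;
  long long C = 0, D = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j];
      const double dy = y[i] - y[j];
      if (dx != 0.0 && dy != 0.0) {
        if ((dx > 0) == (dy > 0)) ++C; else ++D;
      }
    }
  }
  const TieSums tx = tie_sums(x);
  const TieSums ty = tie_sums(y);
  const long double n0 = (long double)n * (n - 1) / 2;
  const long double den = (n0 - tx.s1) * (n0 - ty.s1);
  if (den <= 0) return false;  // all pairs tied in x or in y
  const long double S = (long double)C - (long double)D;
  tau = (double)(S / std::sqrt(den));
  const long double v0 = (long double)n * (n - 1) * (2 * n + 5);
  long double var =
      (v0 - tx.s2 - ty.s2) / 18.0L +
      tx.s3 * ty.s3 / (2.0L * n * (n - 1)) +
      tx.s4 * ty.s4 / (9.0L * n * (n - 1) * (n - 2));
  if (var <= 0) return false;
  // continuity-corrected normal approximation: S is discrete (steps of >= 1)
  long double s_abs = S < 0 ? -S : S;
  long double s_cc = s_abs > 1 ? s_abs - 1 : 0;
  z = (double)((S < 0 ? -s_cc : s_cc) / std::sqrt(var));
  p = 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
  if (p > 1.0) p = 1.0;
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".kendall_tau_b_cpp")]]
NumericVector kendall_tau_b_cpp(NumericVector x, NumericVector y) {
  std::vector<double> xv = as<std::vector<double> >(x);
  std::vector<double> yv = as<std::vector<double> >(y);
  double tau = NA_REAL, z = NA_REAL, p = NA_REAL;
  bool ok = tau_core(xv, yv, tau, z, p);
  NumericVector out = NumericVector::create(
      _["tau"] = ok ? tau : NA_REAL,
      _["z"] = ok ? z : NA_REAL,
      _["p"] = ok ? p : NA_REAL);
  return out;
}

// Mass-univariate screen: X is n x R (overlap measures, complete),
// Y is n x K (scores, may contain NA). Rows with NA in a score column are
// dropped for that column only. Returns R x K matrices of tau, p, n_used.
// [[Rcpp::export(name = ".kendall_screen_cpp")]]
List kendall_screen_cpp(NumericMatrix X, NumericMatrix Y) {
  const int n = X.nrow(), R = X.ncol(), K = Y.ncol();
  if (Y.nrow() != n) stop("X and Y must have the same number of rows");
  NumericMatrix tau(R, K), p(R, K);
  IntegerMatrix nused(R, K);
  std::fill(tau.begin(), tau.end(), NA_REAL);
  std::fill(p.begin(), p.end(), NA_REAL);
  for (int k = 0; k < K; ++k) {
    std::vector<int> idx;
    idx.reserve(n);
    for (int i = 0; i < n; ++i)
      if (!NumericVector::is_na(Y(i, k))) idx.push_back(i);
    const int m = (int)idx.size();
    std::vector<double> yv(m);
    for (int i = 0; i < m; ++i) yv[i] = Y(idx[i], k);
    std::vector<double> xv(m);
    for (int r = 0; r < R; ++r) {
      for (int i = 0; i < m; ++i) xv[i] = X(idx[i], r);
      double t = NA_REAL, z = NA_REAL, pv = NA_REAL;
      bool ok = tau_core(xv, yv, t, z, pv);
      nused(r, k) = m;
      if (ok) { tau(r, k) = t; p(r, k) = pv; }
    }
  }
  return List::create(_["tau"] = tau, _["p"] = p, _["n_used"] = nused);
}
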