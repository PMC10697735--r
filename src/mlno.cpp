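#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Indices (0-based, written 1-based) of the m largest entries of yk,
// ties broken by smallest index, output in increasing index order.
// nth_element finds the m-th largest value; a stable scan collects entries
// above the threshold and fills the remainder with threshold ties.
static void top_m_scan(const double *yk, int n, int m, double *scratch,
                       int *out) {
  std::copy(yk, yk + n, scratch);
  std::nth_element(scratch, scratch + (m - 1), scratch + n,
                   std::greater<double>());
  const double thr = scratch[m - 1];
  int cnt = 0;
  for (int i = 0; i < n && cnt < m; ++i)
    if (yk[i] > thr) out[cnt++] = i + 1;
  for (int i = 0; i < n && cnt < m; ++i)
    if (yk[i] == thr) out[cnt++] = i + 1;
  std::sort(out, out + m);
}

// Liability matrix under the block-factor model
//   y[i,k] = lambda[k] * x[i] + c * f[i, block[k]] + sqrt(1 - c^2) * eps[i,k]
// with exchangeable factor covariance (1-rho)I + rho J realised as
//   f_r = sqrt(1-rho) Z_r + sqrt(rho) Z0   (requires rho >= 0; the R wrapper
// handles rho < 0 by supplying the factor matrix explicitly).
// All draws come from R's RNG stream (norm_rand), so set.seed() and the
// selected normal generator govern the result. Draw order: Z0 (n), then Z
// column-major (n x R), then eps column-major (n x K).
// [[Rcpp::export(".liability_rng")]]
NumericMatrix liability_rng(NumericVector x, NumericVector lambda,
                            IntegerVector block, int R, double cload,
                            double rho) {
  const int n = x.size(), K = lambda.size();
  NumericMatrix y(n, K);
  RNGScope scope;
  const double sr = std::sqrt(rho), s1r = std::sqrt(1.0 - rho);
  const double se = std::sqrt(1.0 - cload * cload);
  std::vector<double> f((size_t)n * R);
  std::vector<double> z0(n);
  for (int i = 0; i < n; ++i) z0[i] = sr * norm_rand();
  for (int r = 0; r < R; ++r) {
    double *fr = &f[(size_t)r * n];
    for (int i = 0; i < n; ++i) fr[i] = s1r * norm_rand() + z0[i];
  }
  for (int k = 0; k < K; ++k) {
    const double lam = lambda[k];
    const double *fb = &f[(size_t)(block[k] - 1) * n];
    double *yk = &y(0, k);
    for (int i = 0; i < n; ++i)
      yk[i] = lam * x[i] + cload * fb[i] + se * norm_rand();
  }
  return y;
}

// Same combination but with a caller-supplied factor matrix f (n x R);
// only the residuals eps are drawn here.
// [[Rcpp::export(".liability_with_factors")]]
NumericMatrix liability_with_factors(NumericVector x, NumericVector lambda,
                                     IntegerVector block, NumericMatrix f,
                                     double cload) {
  const int n = x.size(), K = lambda.size();
  NumericMatrix y(n, K);
  RNGScope scope;
  const double se = std::sqrt(1.0 - cload * cload);
  for (int k = 0; k < K; ++k) {
    const double lam = lambda[k];
    const double *fb = &f(0, block[k] - 1);
    double *yk = &y(0, k);
    for (int i = 0; i < n; ++i)
      yk[i] = lam * x[i] + cload * fb[i] + se * norm_rand();
  }
  return y;
}

// 1-based row indices of the m largest entries per column (the liability
// threshold rule), deterministic under ties.
// [[Rcpp::export(".top_m_index")]]
IntegerMatrix top_m_index(NumericMatrix y, int m) {
  const int n = y.nrow(), K = y.ncol();
  IntegerMatrix idx(m, K);
  std::vector<double> scratch(n);
  for (int k = 0; k < K; ++k)
    top_m_scan(&y(0, k), n, m, scratch.data(), &idx(0, k));
  return idx;
}

// Fused replicate generator for the Monte-Carlo harness: draws the factor
// structure and per-column liabilities with the same stream order as
// .liability_rng, but keeps only one liability column in memory at a time
// and returns the m x K case-index matrix directly. Bit-identical to
// .top_m_index(.liability_rng(...), m) under the same seed.
// [[Rcpp::export(".sim_case_index")]]
IntegerMatrix sim_case_index(NumericVector x, NumericVector lambda,
                             IntegerVector block, int R, double cload,
                             double rho, int m) {
  const int n = x.size(), K = lambda.size();
  IntegerMatrix idx(m, K);
  RNGScope scope;
  const double sr = std::sqrt(rho), s1r = std::sqrt(1.0 - rho);
  const double se = std::sqrt(1.0 - cload * cload);
  std::vector<double> f((size_t)n * R);
  std::vector<double> z0(n), yk(n), scratch(n);
  for (int i = 0; i < n; ++i) z0[i] = sr * norm_rand();
  for (int r = 0; r < R; ++r) {
    double *fr = &f[(size_t)r * n];
    for (int i = 0; i < n; ++i) fr[i] = s1r * norm_rand() + z0[i];
  }
  for (int k = 0; k < K; ++k) {
    const double lam = lambda[k];
    const double *fb = &f[(size_t)(block[k] - 1) * n];
    for (int i = 0; i < n; ++i)
      yk[i] = lam * x[i] + cload * fb[i] + se * norm_rand();
    top_m_scan(yk.data(), n, m, scratch.data(), &idx(0, k));
  }
  return idx;
}
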