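#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter applied down each column of X
// (samples run down rows, one column per channel). Stateless across columns.
static void filt_col(const double* x, double* y, int T,
                     const std::vector<double>& b, const std::vector<double>& a,
                     std::vector<double>& z) {
  const int n = (int)b.size();  // b, a padded to equal length, a[0] == 1
  std::fill(z.begin(), z.end(), 0.0);
  for (int t = 0; t < T; ++t) {
    const double xt = x[t];
    const double yt = b[0] * xt + z[0];
    for (int k = 1; k < n; ++k) z[k - 1] = b[k] * xt - a[k] * yt + z[k];
    y[t] = yt;
  }
}

// Zero-phase (forward-backward) IIR filtering of each column of X with
// odd-reflection padding of `pad` samples at both ends to suppress edge
// transients. Returns a matrix of the same shape as X.
// [[Rcpp::export(name = ".filtfilt_cols")]]
NumericMatrix filtfilt_cols(NumericMatrix X, NumericVector b, NumericVector a,
                            int pad) {
  const int T = X.nrow(), C = X.ncol();
  if (T < 2) stop("need at least 2 samples to filter");
  if (pad < 0 || pad > T - 1) pad = std::min(T - 1, std::max(0, pad));
  const int n = std::max(b.size(), a.size());
  std::vector<double> bb(n, 0.0), aa(n, 0.0);
  const double a0 = a[0];
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i] / a0;

  NumericMatrix Y(T, C);
  const int Tp = T + 2 * pad;
  std::vector<double> u(Tp), v(Tp), z(n, 0.0);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    // odd reflection about the end points
    for (int i = 0; i < pad; ++i) u[i] = 2.0 * x[0] - x[pad - i];
    for (int t = 0; t < T; ++t) u[pad + t] = x[t];
    for (int i = 0; i < pad; ++i) u[pad + T + i] = 2.0 * x[T - 1] - x[T - 2 - i];
    // forward pass
    filt_col(u.data(), v.data(), Tp, bb, aa, z);
    // backward pass (filter the reversed forward output, in place into u)
    std::reverse(v.begin(), v.end());
    filt_col(v.data(), u.data(), Tp, bb, aa, z);
    std::reverse(u.begin(), u.end());
    double* y = &Y(0, c);
    for (int t = 0; t < T; ++t) y[t] = u[pad + t];
  }
  return Y;
}

// In-place variant of filtfilt_cols: overwrites X with the filtered signal
// (used by the pipeline to halve peak memory on multi-GB recordings).
// [[Rcpp::export(name = ".filtfilt_cols_inplace")]]
void filtfilt_cols_inplace(NumericMatrix X, NumericVector b, NumericVector a,
                           int pad) {
  const int T = X.nrow(), C = X.ncol();
  if (T < 2) stop("need at least 2 samples to filter");
  if (pad < 0 || pad > T - 1) pad = std::min(T - 1, std::max(0, pad));
  const int n = std::max(b.size(), a.size());
  std::vector<double> bb(n, 0.0), aa(n, 0.0);
  const double a0 = a[0];
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i] / a0;
  const int Tp = T + 2 * pad;
  std::vector<double> u(Tp), v(Tp), z(n, 0.0);
  for (int c = 0; c < C; ++c) {
    double* x = &X(0, c);
    for (int i = 0; i < pad; ++i) u[i] = 2.0 * x[0] - x[pad - i];
    for (int t = 0; t < T; ++t) u[pad + t] = x[t];
    for (int i = 0; i < pad; ++i) u[pad + T + i] = 2.0 * x[T - 1] - x[T - 2 - i];
    filt_col(u.data(), v.data(), Tp, bb, aa, z);
    std::reverse(v.begin(), v.end());
    filt_col(v.data(), u.data(), Tp, bb, aa, z);
    std::reverse(u.begin(), u.end());
    for (int t = 0; t < T; ++t) x[t] = u[pad + t];
  }
}

// X += Y, elementwise, in place (avoids a third allocation for big sums).
// [[Rcpp::export(name = ".add_inplace")]]
void add_inplace(NumericMatrix X, NumericMatrix Y) {
  if (X.nrow() != Y.nrow() || X.ncol() != Y.ncol()) stop("shape mismatch");
  const R_xlen_t n = X.size();
  double* x = X.begin();
  const double* y = Y.begin();
  for (R_xlen_t i = 0; i < n; ++i) x[i] += y[i];
}

// X += white Gaussian noise with standard deviation sd, using R's RNG
// (so draws are reproducible under set.seed), in place.
// [[Rcpp::export(name = ".add_white_inplace")]]
void add_white_inplace(NumericMatrix X, double sd) {
  const R_xlen_t n = X.size();
  double* x = X.begin();
  for (R_xlen_t i = 0; i < n; ++i) x[i] += R::rnorm(0.0, sd);
}

// First-order autoregressive recursion y[t] = rho * y[t-1] + x[t] applied
// down each column (used to colour noise innovations in the generator).
// [[Rcpp::export(name = ".ar1_cols")]]
NumericMatrix ar1_cols(NumericMatrix X, double rho) {
  const int T = X.nrow(), C = X.ncol();
  NumericMatrix Y(T, C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    double* y = &Y(0, c);
    double prev = 0.0;
    for (int t = 0; t < T; ++t) {
      prev = rho * prev + x[t];
      y[t] = prev;
    }
  }
  return Y;
}
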