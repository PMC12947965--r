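#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sliding-window sample entropy with a fixed (global) tolerance r.
//
// For every sample i the window [i - n_left, i + n_right] (clipped at the
// record edges) is scanned; templates of length m are compared under the
// Chebyshev distance, B counts matching template pairs of length m, A the
// pairs that still match when extended to length m + 1, and the entropy is
// -log(A / B). Windows where A or B is zero are returned as NA together
// with the raw counts so the caller can apply its substitution policy.
//
// [[Rcpp::export]]
List fse_window_counts(NumericVector x, int n_left, int n_right,
                       double r, int m) {
  const int n = x.size();
  NumericVector val(n);
  IntegerVector acnt(n), bcnt(n);
  for (int i = 0; i < n; ++i) {
    const int lo = std::max(0, i - n_left);
    const int hi = std::min(n - 1, i + n_right);
    const int len = hi - lo + 1;
    const int nt = len - m;  // templates that admit an (m+1)-th element
    long long A = 0, B = 0;
    for (int a = 0; a < nt; ++a) {
      for (int b = a + 1; b < nt; ++b) {
        bool match = true;
        for (int k = 0; k < m; ++k) {
          if (std::fabs(x[lo + a + k] - x[lo + b + k]) > r) {
            match = false;
            break;
          }
        }
        if (!match) continue;
        ++B;
        if (std::fabs(x[lo + a + m] - x[lo + b + m]) <= r) ++A;
      }
    }
    acnt[i] = static_cast<int>(A);
    bcnt[i] = static_cast<int>(B);
    val[i] = (A > 0 && B > 0)
      ? -std::log(static_cast<double>(A) / static_cast<double>(B))
      : NA_REAL;
  }
  return List::create(_["value"] = val, _["A"] = acnt, _["B"] = bcnt);
}

// Least-mean-squares adaptive cancellation. x is the primary input, ref the
// synthesized cardiac reference; M taps, step mu (already normalized by the
// caller). Returns the cancellation output y and the residual e = x - y.
//
// [[Rcpp::export]]
List lms_cancel_cpp(NumericVector x, NumericVector ref, int M, double mu) {
  const int n = x.size();
  NumericVector y(n), e(n);
  std::vector<double> w(M, 0.0);
  bool diverged = false;
  for (int i = 0; i < n; ++i) {
    const int kmax = std::min(M, i + 1);
    double yi = 0.0;
    for (int k = 0; k < kmax; ++k) yi += w[k] * ref[i - k];
    y[i] = yi;
    const double err = x[i] - yi;
    e[i] = err;
    if (!std::isfinite(err)) {
      diverged = true;
      break;
    }
    const double g = 2.0 * mu * err;
    for (int k = 0; k < kmax; ++k) w[k] += g * ref[i - k];
  }
  return List::create(_["y"] = y, _["e"] = e, _["diverged"] = diverged);
}
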