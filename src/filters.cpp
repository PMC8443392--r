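#include <Rcpp.h>
using namespace Rcpp;

// Scalar Kalman predict/update recursion over one window.
// [[Rcpp::export]]
List kalman_scalar_cpp(NumericVector y, double A, double H, double Q,
                       double R, double x0, double P0) {
  if (R <= 0) stop("parameter error: R must be > 0");
  int n = y.size();
  NumericVector xs(n), Ps(n);
  double x = x0, P = P0;
  for (int k = 0; k < n; ++k) {
    double xm = A * x;
    double Pm = A * A * P + Q;
    double K = Pm * H / (H * H * Pm + R);
    x = xm + K * (y[k] - H * xm);
    P = (1.0 - K * H) * Pm;
    xs[k] = x;
    Ps[k] = P;
  }
  return List::create(_["x"] = xs, _["P"] = Ps);
}

// One LMS pass over the window; returns the pass MSE. Weights updated in place.
static double lms_pass(const NumericVector& d, const NumericVector& r,
                       std::vector<double>& w, double mu) {
  int n = d.size(), M = w.size();
  double sse = 0.0;
  for (int k = 0; k < n; ++k) {
    double rhat = 0.0;
    int mmax = std::min(M - 1, k);
    for (int m = 0; m <= mmax; ++m) rhat += w[m] * r[k - m];
    double e = d[k] - rhat;
    sse += e * e;
    for (int m = 0; m <= mmax; ++m) w[m] += 2.0 * mu * e * r[k - m];
  }
  return sse / n;
}

// LMS adaptive fit: repeated passes until |delta MSE| < tol or max_epochs.
// [[Rcpp::export]]
List lms_fit_cpp(NumericVector d, NumericVector r, int M, double mu,
                 int max_epochs, double tol, NumericVector w0) {
  std::vector<double> w(w0.begin(), w0.end());
  double mse = R_PosInf, prev = R_PosInf;
  int ep = 0;
  bool diverged = false;
  for (ep = 0; ep < max_epochs; ++ep) {
    mse = lms_pass(d, r, w, mu);
    if (!std::isfinite(mse) || mse > 1e6) { diverged = true; break; }
    if (ep > 0 && std::fabs(prev - mse) < tol) { ++ep; break; }
    prev = mse;
  }
  return List::create(_["mse"] = mse, _["epochs"] = ep,
                      _["weights"] = NumericVector(w.begin(), w.end()),
                      _["diverged"] = diverged);
}

// Final LMS MSE of the desired signal against every dictionary atom.
// [[Rcpp::export]]
List lms_dict_cpp(NumericVector d, NumericMatrix D, int M, double mu,
                  int max_epochs, double tol) {
  int natoms = D.ncol();
  NumericVector out(natoms);
  bool diverged = false;
  for (int j = 0; j < natoms; ++j) {
    NumericVector r = D(_, j);
    std::vector<double> w(M, 0.0);
    double mse = R_PosInf, prev = R_PosInf;
    for (int ep = 0; ep < max_epochs; ++ep) {
      mse = lms_pass(d, r, w, mu);
      if (!std::isfinite(mse) || mse > 1e6) { diverged = true; break; }
      if (ep > 0 && std::fabs(prev - mse) < tol) break;
      prev = mse;
    }
    out[j] = mse;
    if (diverged) break;
  }
  return List::create(_["mse"] = out, _["diverged"] = diverged);
}
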