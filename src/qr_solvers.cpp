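#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact weighted quantile regression with intercept + one slope, solved by
// enumerating basic solutions of the check-loss linear program.  An optimal
// vertex of
//   min tau*1'u + (1-tau)*1'v  s.t.  X b + u - v = y,  u,v >= 0
// interpolates two observations with distinct x, so scanning all such lines
// (loss decomposed into tau-free positive/negative parts reused across tau
// levels) yields the exact minimizer.  Complexity O(n^3 + n^2 T).
//
// Returns per tau: intercept, slope, objective (with weights w applied);
// status 0 ok, 1 fewer than two distinct x among positive weights.
// [[Rcpp::export]]
List cpp_qr_pairs(NumericVector x, NumericVector y, NumericVector w,
                  NumericVector taus) {
  const int n = x.size(), T = taus.size();
  NumericVector a(T, NA_REAL), b(T, NA_REAL),
    obj(T, R_PosInf);
  bool any_pair = false;
  std::vector<double> spos(1), sneg(1);
  for (int i = 0; i < n; ++i) {
    if (w[i] <= 0.0) continue;
    for (int j = i + 1; j < n; ++j) {
      if (w[j] <= 0.0) continue;
      double dx = x[j] - x[i];
      if (dx == 0.0) continue;
      any_pair = true;
      double slope = (y[j] - y[i]) / dx;
      double icept = y[i] - slope * x[i];
      double sp = 0.0, sn = 0.0;
      for (int k = 0; k < n; ++k) {
        double r = y[k] - icept - slope * x[k];
        if (r > 0.0)      sp += w[k] * r;
        else if (r < 0.0) sn -= w[k] * r;
      }
      for (int t = 0; t < T; ++t) {
        double loss = taus[t] * sp + (1.0 - taus[t]) * sn;
        double thr = R_FINITE(obj[t])
          ? obj[t] - 1e-12 * (1.0 + std::abs(obj[t])) : R_PosInf;
        if (loss < thr) {
          obj[t] = loss; a[t] = icept; b[t] = slope;
        }
      }
    }
  }
  int status = any_pair ? 0 : 1;
  return List::create(_["intercept"] = a, _["slope"] = b,
                      _["objective"] = obj, _["status"] = status);
}

// Exact weighted quantile (intercept-only check-loss fit): smallest data
// value at which the cumulative weight reaches tau * total.  Candidates are
// the data values themselves; ties break toward the smaller value.
// [[Rcpp::export]]
NumericVector cpp_weighted_quantile(NumericVector y, NumericVector w,
                                    NumericVector taus) {
  const int n = y.size(), T = taus.size();
  IntegerVector ord = seq(0, n - 1);
  std::sort(ord.begin(), ord.end(),
            [&](int i, int j) { return y[i] < y[j]; });
  double W = 0.0;
  for (int i = 0; i < n; ++i) W += w[i];
  NumericVector out(T);
  for (int t = 0; t < T; ++t) {
    double target = taus[t] * W, cum = 0.0;
    double val = y[ord[n - 1]];
    for (int i = 0; i < n; ++i) {
      cum += w[ord[i]];
      if (cum >= target - 1e-12 * W) { val = y[ord[i]]; break; }
    }
    out[t] = val;
  }
  return out;
}

// Local-linear quantile regression curve: at every grid point solve the
// Gaussian-kernel-weighted check-loss fit of intercept + slope by the same
// basic-solution enumeration.  Observations whose kernel weight is below
// 1e-12 of the local maximum are dropped.  Grid points outside the observed
// covariate range are clamped to the data boundary (constant extension: the
// local line is neither fitted nor evaluated beyond the data).  Grid points
// with fewer than two distinct covariate values in the effective window
// fall back to a weighted-quantile intercept (slope 0); both fallbacks are
// flagged.
// [[Rcpp::export]]
List cpp_lpqr_curve(NumericVector x, NumericVector y, NumericVector xgrid,
                    NumericVector taus, double h) {
  const int n = x.size(), G = xgrid.size(), T = taus.size();
  NumericMatrix a0(G, T), a1(G, T);
  IntegerVector flag(G);
  double xmin = R_PosInf, xmax = R_NegInf;
  for (int k = 0; k < n; ++k) {
    if (x[k] < xmin) xmin = x[k];
    if (x[k] > xmax) xmax = x[k];
  }
  std::vector<double> w(n);
  std::vector<int> idx; idx.reserve(n);
  for (int g = 0; g < G; ++g) {
    double x0 = xgrid[g], wmax = 0.0;
    if (x0 < xmin)      { x0 = xmin; flag[g] = 2; }
    else if (x0 > xmax) { x0 = xmax; flag[g] = 2; }
    for (int k = 0; k < n; ++k) {
      double u = (x0 - x[k]) / h;
      w[k] = std::exp(-0.5 * u * u);
      if (w[k] > wmax) wmax = w[k];
    }
    idx.clear();
    for (int k = 0; k < n; ++k)
      if (w[k] > 1e-12 * wmax) idx.push_back(k);
    const int m = (int)idx.size();
    // exact vertex enumeration over the effective window
    std::vector<double> best(T, R_PosInf), ba(T, NA_REAL), bb(T, NA_REAL);
    bool any_pair = false;
    for (int ii = 0; ii < m; ++ii) {
      int i = idx[ii];
      for (int jj = ii + 1; jj < m; ++jj) {
        int j = idx[jj];
        double dx = x[j] - x[i];
        if (dx == 0.0) continue;
        any_pair = true;
        double slope = (y[j] - y[i]) / dx;
        double icept = y[i] - slope * x[i];
        double sp = 0.0, sn = 0.0;
        for (int kk = 0; kk < m; ++kk) {
          int k = idx[kk];
          double r = y[k] - icept - slope * x[k];
          if (r > 0.0)      sp += w[k] * r;
          else if (r < 0.0) sn -= w[k] * r;
        }
        for (int t = 0; t < T; ++t) {
          double loss = taus[t] * sp + (1.0 - taus[t]) * sn;
          double thr = R_FINITE(best[t])
            ? best[t] - 1e-12 * (1.0 + std::abs(best[t])) : R_PosInf;
          if (loss < thr) {
            best[t] = loss; ba[t] = icept; bb[t] = slope;
          }
        }
      }
    }
    if (!any_pair) {
      // intercept-only fallback on the effective window
      NumericVector yy(m), ww(m);
      for (int kk = 0; kk < m; ++kk) { yy[kk] = y[idx[kk]]; ww[kk] = w[idx[kk]]; }
      NumericVector q = cpp_weighted_quantile(yy, ww, taus);
      for (int t = 0; t < T; ++t) { a0(g, t) = q[t]; a1(g, t) = 0.0; }
      flag[g] = 1;
    } else {
      for (int t = 0; t < T; ++t) {
        a0(g, t) = ba[t] + bb[t] * x0;   // fitted value at x0
        a1(g, t) = bb[t];
      }
    }
  }
  return List::create(_["a0"] = a0, _["a1"] = a1, _["flag"] = flag);
}
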