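#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cyclic coordinate descent for one Poisson GLM with log link and offset.
//
// Minimizes f(beta) = sum_i exp(eta_i) - sum_i y_i * eta_i with
// eta = offset + D beta, visiting coordinates in fixed ascending order.
// Each coordinate takes a 1-d Newton step delta = -g/c, clipped to
// |delta| <= step_cap, then step-halved until f does not increase, so f
// is exactly non-increasing over every cycle.  The response enters only
// through its nonzeros (yi: 0-based positions, yx: values) via the
// cached cross-products s_k = sum_i D_ik y_i and the linear term
// sum_i y_i eta_i.  eta is clamped at eta_clamp inside every exp().
//
// [[Rcpp::export]]
List ccd_fit_cpp(IntegerVector yi, NumericVector yx, NumericMatrix D,
                 NumericVector offset, NumericVector beta0,
                 int max_cycles, double tol, double step_cap,
                 int max_halvings, double eta_clamp) {
  const int N = D.nrow(), J = D.ncol(), nnz = yi.size();
  NumericVector beta = clone(beta0);
  NumericVector eta(N), mu(N);

  for (int i = 0; i < N; i++) eta[i] = offset[i];
  for (int k = 0; k < J; k++) {
    const double bk = beta[k];
    if (bk != 0.0)
      for (int i = 0; i < N; i++) eta[i] += D(i, k) * bk;
  }

  double expsum = 0.0;
  int n_clamp = 0;
  for (int i = 0; i < N; i++) {
    double e = eta[i];
    if (e > eta_clamp) { e = eta_clamp; n_clamp++; }
    mu[i] = std::exp(e);
    expsum += mu[i];
  }

  // sparse caches: s_k = sum_i D_ik y_i, ylin = sum_i y_i eta_i
  NumericVector s(J);
  std::vector<bool> allzero(J, true);
  double ylin = 0.0;
  for (int t = 0; t < nnz; t++) ylin += yx[t] * eta[yi[t]];
  for (int k = 0; k < J; k++) {
    double sk = 0.0;
    for (int t = 0; t < nnz; t++) sk += yx[t] * D(yi[t], k);
    s[k] = sk;
    for (int i = 0; i < N; i++)
      if (D(i, k) != 0.0) { allzero[k] = false; break; }
  }

  double f = expsum - ylin;
  const double f0 = f;
  int n_skip = 0, cycles = 0;
  double maxchg_last = 0.0;

  for (int cyc = 0; cyc < max_cycles; cyc++) {
    double maxchg = 0.0;
    for (int k = 0; k < J; k++) {
      if (allzero[k]) continue;
      double g = -s[k], c = 0.0;
      for (int i = 0; i < N; i++) {
        const double dk = D(i, k);
        if (dk != 0.0) { g += dk * mu[i]; c += dk * dk * mu[i]; }
      }
      if (!(c > 0.0) || !R_finite(g) || !R_finite(c)) { n_skip++; continue; }
      double delta = -g / c;
      if (delta > step_cap) delta = step_cap;
      else if (delta < -step_cap) delta = -step_cap;
      if (delta == 0.0) continue;

      double new_expsum = 0.0;
      bool accepted = false;
      for (int h = 0; h <= max_halvings; h++) {
        new_expsum = 0.0;
        for (int i = 0; i < N; i++) {
          double e = eta[i] + delta * D(i, k);
          if (e > eta_clamp) e = eta_clamp;
          new_expsum += std::exp(e);
        }
        const double fnew = new_expsum - (ylin + delta * s[k]);
        if (R_finite(fnew) && fnew <= f) { accepted = true; break; }
        delta *= 0.5;
      }
      if (!accepted) continue;

      beta[k] += delta;
      for (int i = 0; i < N; i++) {
        eta[i] += delta * D(i, k);
        double e = eta[i];
        if (e > eta_clamp) { e = eta_clamp; n_clamp++; }
        mu[i] = std::exp(e);
      }
      expsum = new_expsum;
      ylin += delta * s[k];
      f = expsum - ylin;
      const double ad = std::fabs(delta);
      if (ad > maxchg) maxchg = ad;
    }
    cycles++;
    maxchg_last = maxchg;
    if (maxchg < tol) break;
  }

  return List::create(_["beta"] = beta, _["eta"] = eta,
                      _["objective"] = f, _["decrease"] = f0 - f,
                      _["cycles"] = cycles, _["max_change"] = maxchg_last,
                      _["n_skipped"] = n_skip, _["n_clamped"] = n_clamp);
}
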