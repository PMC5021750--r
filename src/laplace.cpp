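// Laplace-approximated marginal negative log-likelihood for the Monod-type
// growth mixed model.  Observations are ordered in contiguous clone blocks
// (see .prep_growth_data); the conditional mode of each clone's random
// effects is found by a damped penalised Gauss-Newton search, and the
// Laplace determinant uses the exact Hessian (Gauss-Newton fallback when
// it loses positive definiteness at the mode).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KS_FLOOR = 1e-8;

// residual sum of squares + penalty for one clone at random effects b[3]
// (inactive entries zero); returns false when KS drops below the floor.
static bool clone_h(const double* y, const double* S, int ni,
                    double g0, double ginf, double Kfix,
                    const double* b, const double* inv_tau2,
                    double inv2sig2, double& h, double& rss) {
  double g0c = g0 + b[0], ginfc = ginf + b[1], Kc = Kfix + b[2];
  if (Kc <= KS_FLOOR) return false;
  double acc = 0.0;
  for (int j = 0; j < ni; ++j) {
    double u = S[j] / (S[j] + Kc);
    double r = y[j] - (g0c + (ginfc - g0c) * u);
    acc += r * r;
  }
  rss = acc;
  double pen = 0.0;
  for (int k = 0; k < 3; ++k)
    if (inv_tau2[k] > 0.0) pen += b[k] * b[k] * inv_tau2[k];
  h = acc * inv2sig2 + 0.5 * pen;
  return true;
}

// gradient and (optionally exact) Hessian in the active dimensions
static void clone_derivs(const double* y, const double* S, int ni,
                         double g0, double ginf, double Kfix,
                         const double* b, const double* inv_tau2,
                         double inv_sig2, const int* act, int qa,
                         bool exact, double* grad, double* H) {
  double g0c = g0 + b[0], ginfc = ginf + b[1], Kc = Kfix + b[2];
  for (int k = 0; k < qa; ++k) grad[k] = 0.0;
  for (int k = 0; k < qa * qa; ++k) H[k] = 0.0;
  double d[3], dd[3][3];
  for (int j = 0; j < ni; ++j) {
    double den = S[j] + Kc;
    double u = S[j] / den;
    double r = y[j] - (g0c + (ginfc - g0c) * u);
    d[0] = 1.0 - u;                       // d f / d g0
    d[1] = u;                             // d f / d ginf
    d[2] = -(ginfc - g0c) * S[j] / (den * den);   // d f / d KS
    for (int a = 0; a < qa; ++a) {
      grad[a] -= r * d[act[a]];
      for (int bb = a; bb < qa; ++bb) {
        double cross = d[act[a]] * d[act[bb]];
        if (exact) {
          int ia = act[a], ib = act[bb];
          double curv = 0.0;
          if (ia == 2 && ib == 2)
            curv = 2.0 * (ginfc - g0c) * S[j] / (den * den * den);
          else if ((ia == 0 && ib == 2) || (ia == 2 && ib == 0))
            curv = S[j] / (den * den);
          else if ((ia == 1 && ib == 2) || (ia == 2 && ib == 1))
            curv = -S[j] / (den * den);
          cross -= r * curv;
        }
        H[a * qa + bb] += cross;
      }
    }
  }
  for (int a = 0; a < qa; ++a) {
    grad[a] = grad[a] * inv_sig2 + b[act[a]] * inv_tau2[act[a]];
    for (int bb = a; bb < qa; ++bb) {
      double v = H[a * qa + bb] * inv_sig2;
      if (bb == a) v += inv_tau2[act[a]];
      H[a * qa + bb] = v;
      H[bb * qa + a] = v;
    }
  }
}

// solve H x = g for qa <= 3; returns false if the system is singular
static bool solve_small(const double* H, const double* g, int qa,
                        double* x) {
  if (qa == 1) {
    if (H[0] <= 0.0) return false;
    x[0] = g[0] / H[0];
    return true;
  }
  if (qa == 2) {
    double det = H[0] * H[3] - H[1] * H[1];
    if (det == 0.0 || !std::isfinite(det)) return false;
    x[0] = (H[3] * g[0] - H[1] * g[1]) / det;
    x[1] = (H[0] * g[1] - H[1] * g[0]) / det;
    return true;
  }
  double a = H[0], b = H[1], c = H[2], e = H[4], f = H[5], k = H[8];
  double A = e * k - f * f, B = c * f - b * k, C = b * f - c * e;
  double det = a * A + b * B + c * C;
  if (det == 0.0 || !std::isfinite(det)) return false;
  double i22 = a * k - c * c, i23 = b * c - a * f, i33 = a * e - b * b;
  x[0] = (A * g[0] + B * g[1] + C * g[2]) / det;
  x[1] = (B * g[0] + i22 * g[1] + i23 * g[2]) / det;
  x[2] = (C * g[0] + i23 * g[1] + i33 * g[2]) / det;
  return true;
}

// log determinant for qa <= 3 symmetric; NaN when not positive
static double logdet_small(const double* H, int qa) {
  double det;
  if (qa == 1) det = H[0];
  else if (qa == 2) det = H[0] * H[3] - H[1] * H[1];
  else {
    double a = H[0], b = H[1], c = H[2], e = H[4], f = H[5], k = H[8];
    det = a * (e * k - f * f) - b * (b * k - c * f) + c * (b * f - c * e);
  }
  if (!(det > 0.0) || !std::isfinite(det)) return NA_REAL;
  return std::log(det);
}

// [[Rcpp::export(name = ".laplace_core_cpp")]]
List laplace_core_cpp(NumericVector y, NumericVector S, IntegerVector ends,
                      double g0, double ginf, NumericVector Kfix,
                      NumericVector tau3, double sigma,
                      NumericMatrix b_start,
                      int max_iter, double tol) {
  const int m = ends.size();
  const double inv_sig2 = 1.0 / (sigma * sigma);
  const double inv2sig2 = 0.5 * inv_sig2;
  double inv_tau2[3];
  int act[3], qa = 0;
  for (int k = 0; k < 3; ++k) {
    if (tau3[k] > 1e-7) {
      inv_tau2[k] = 1.0 / (tau3[k] * tau3[k]);
      act[qa++] = k;
    } else inv_tau2[k] = 0.0;
  }
  NumericMatrix b_out(m, 3);
  NumericVector rss_out(m), logdet_out(m), pen_out(m);
  bool all_ok = true;
  int start = 0;
  double grad[3], Hbuf[9], He[9], step[3], bq[3], btry[3];

  for (int i = 0; i < m && all_ok; ++i) {
    int e = ends[i], ni = e - start;
    const double* yy = REAL(y) + start;
    const double* ss = REAL(S) + start;
    double b[3] = {0.0, 0.0, 0.0};
    for (int k = 0; k < qa; ++k) b[act[k]] = b_start(i, act[k]);
    double h, rss;
    if (!clone_h(yy, ss, ni, g0, ginf, Kfix[i], b, inv_tau2, inv2sig2,
                 h, rss)) {
      for (int k = 0; k < 3; ++k) b[k] = 0.0;
      if (!clone_h(yy, ss, ni, g0, ginf, Kfix[i], b, inv_tau2, inv2sig2,
                   h, rss)) { all_ok = false; break; }
    }
    if (qa > 0) {
      for (int it = 0; it < max_iter; ++it) {
        clone_derivs(yy, ss, ni, g0, ginf, Kfix[i], b, inv_tau2,
                     inv_sig2, act, qa, false, grad, Hbuf);
        if (!solve_small(Hbuf, grad, qa, step)) break;
        double alpha = 1.0, h_new, rss_new;
        bool improved = false;
        for (int ls = 0; ls < 25; ++ls) {
          for (int k = 0; k < qa; ++k)
            bq[k] = b[act[k]] - alpha * step[k];
          for (int k = 0; k < 3; ++k) btry[k] = 0.0;
          for (int k = 0; k < qa; ++k) btry[act[k]] = bq[k];
          if (clone_h(yy, ss, ni, g0, ginf, Kfix[i], btry, inv_tau2,
                      inv2sig2, h_new, rss_new) &&
              h_new <= h + 1e-12) { improved = true; break; }
          alpha *= 0.5;
        }
        if (!improved) break;
        double moved = 0.0;
        for (int k = 0; k < qa; ++k) {
          double dk = alpha * step[k];
          if (std::fabs(dk) > moved) moved = std::fabs(dk);
          b[act[k]] = b[act[k]] - dk;
        }
        h = h_new; rss = rss_new;
        if (moved < tol) break;
      }
      clone_derivs(yy, ss, ni, g0, ginf, Kfix[i], b, inv_tau2, inv_sig2,
                   act, qa, true, grad, He);
      double ld = logdet_small(He, qa);
      if (!std::isfinite(ld)) {
        clone_derivs(yy, ss, ni, g0, ginf, Kfix[i], b, inv_tau2, inv_sig2,
                     act, qa, false, grad, Hbuf);
        ld = logdet_small(Hbuf, qa);
        if (!std::isfinite(ld)) { all_ok = false; break; }
      }
      logdet_out[i] = ld;
      double pen = 0.0;
      for (int k = 0; k < qa; ++k)
        pen += b[act[k]] * b[act[k]] * inv_tau2[act[k]];
      pen_out[i] = pen;
    }
    rss_out[i] = rss;
    for (int k = 0; k < 3; ++k) b_out(i, k) = b[k];
    start = e;
  }
  return List::create(_["ok"] = all_ok, _["b"] = b_out,
                      _["rss"] = rss_out, _["logdet"] = logdet_out,
                      _["pen"] = pen_out, _["qa"] = qa);
}
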