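#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-compartment disposition with zero-order (infusion) input, closed form.
// Unit-impulse (bolus) response of the central concentration is
//   h(t) = c1*exp(-l1*t) + c2*exp(-l2*t),
// l1 > l2 the hybrid rate constants, c1 + c2 = 1/V1.

struct Macro {
  double l1, l2, c1, c2;
};

static inline Macro macro_coefs(double CL, double V1, double V2, double Q) {
  double k10 = CL / V1;
  double k12 = (V1 > 0.0) ? Q / V1 : 0.0;
  double k21 = (V2 > 0.0) ? Q / V2 : 0.0;
  double s = k10 + k12 + k21;
  double p = k10 * k21;
  double disc = s * s - 4.0 * p;
  if (disc < 0.0) disc = 0.0;
  double sq = std::sqrt(disc);
  // stable quadratic roots: compute the large root first, small one by Vieta
  double l1 = 0.5 * (s + sq);
  double l2 = (l1 > 0.0) ? p / l1 : 0.0;
  // repeated-root guard: separate slightly so the partial fractions stay finite
  if (l1 - l2 < 1e-10 * l1) l2 = l1 * (1.0 - 1e-7);
  Macro m;
  m.l1 = l1;
  m.l2 = l2;
  double den = V1 * (l1 - l2);
  m.c1 = (l1 - k21) / den;
  m.c2 = (k21 - l2) / den;
  return m;
}

// (1 - exp(-lam*t))/lam, stable for small lam*t
static inline double iexp(double lam, double t) {
  double x = lam * t;
  if (x < 1e-8) return t * (1.0 - 0.5 * x);
  return -std::expm1(-x) / lam;
}

// integral_0^u (1 - exp(-lam*t)) dt / lam  =  (u - iexp(lam,u))/lam, stable
static inline double i2exp(double lam, double u) {
  double x = lam * u;
  if (x < 1e-6) return 0.5 * u * u * (1.0 - x / 3.0);
  return (u - iexp(lam, u)) / lam;
}

// concentration contribution of one infusion dose at time-since-start s
static inline double conc_one(const Macro &m, double rate, double dur, double s) {
  if (s <= 0.0) return 0.0;
  double out = 0.0;
  double u = (s < dur) ? s : dur;
  // during-infusion accumulation up to u, then decay for (s-u)
  for (int k = 0; k < 2; ++k) {
    double c = (k == 0) ? m.c1 : m.c2;
    double l = (k == 0) ? m.l1 : m.l2;
    if (c == 0.0) continue;
    double at_u = rate * c * iexp(l, u);
    out += (s <= dur) ? at_u : at_u * std::exp(-l * (s - dur));
  }
  return out;
}

// integral of conc_one from 0 to s (s since dose start); s may be +Inf
static inline double auc_one(const Macro &m, double amt, double rate,
                             double dur, double s, double CL) {
  if (s <= 0.0) return 0.0;
  if (!R_finite(s)) return amt / CL;
  double u = (s < dur) ? s : dur;
  double out = 0.0;
  for (int k = 0; k < 2; ++k) {
    double c = (k == 0) ? m.c1 : m.c2;
    double l = (k == 0) ? m.l1 : m.l2;
    if (c == 0.0) continue;
    out += rate * c * i2exp(l, u);               // during-infusion part
    if (s > dur) {
      double amt_end = rate * c * iexp(l, dur);  // term amplitude at end of infusion
      out += amt_end * iexp(l, s - dur);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_macro_coefs(double CL, double V1, double V2, double Q) {
  Macro m = macro_coefs(CL, V1, V2, Q);
  return NumericVector::create(_["alpha"] = m.l1, _["beta"] = m.l2,
                               _["c1"] = m.c1, _["c2"] = m.c2);
}

// [[Rcpp::export]]
NumericVector cpp_conc2(NumericVector t, NumericVector dstart, NumericVector damt,
                        NumericVector ddur, double CL, double V1, double V2,
                        double Q) {
  Macro m = macro_coefs(CL, V1, V2, Q);
  int nt = t.size(), nd = dstart.size();
  NumericVector out(nt);
  for (int i = 0; i < nt; ++i) {
    double acc = 0.0;
    for (int d = 0; d < nd; ++d) {
      double s = t[i] - dstart[d];
      if (s <= 0.0) continue;
      acc += conc_one(m, damt[d] / ddur[d], ddur[d], s);
    }
    out[i] = acc;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_auc2(NumericVector dstart, NumericVector damt, NumericVector ddur,
                double CL, double V1, double V2, double Q, double t0, double t1) {
  Macro m = macro_coefs(CL, V1, V2, Q);
  int nd = dstart.size();
  double out = 0.0;
  for (int d = 0; d < nd; ++d) {
    double rate = damt[d] / ddur[d];
    out += auc_one(m, damt[d], rate, ddur[d], t1 - dstart[d], CL) -
           auc_one(m, damt[d], rate, ddur[d], t0 - dstart[d], CL);
  }
  return out;
}

// ---------------------------------------------------------------------------
// FOCE-I / Laplace machinery.
//
// Per-subject penalized objective (NONMEM-style, full constants):
//   g(eta) = sum_j [ log(2*pi*V_j) + (y_j - f_j)^2 / V_j ]
//          + d*log(2*pi) + log|Omega| + eta' Omega^-1 eta
// with V_j = sp2*f_j^2 + sa2 evaluated at the eta-conditional prediction
// (the eta-eps interaction).  The subject's -2 log marginal likelihood is
// approximated by Laplace around the mode eta-hat:
//   -2logL = g(eta_hat) - d*log(2*pi) + log|H|,   H = hessian(g/2).
// H defaults to the FOCE-I (Gauss-Newton/Fisher) form
//   H = Omega^-1 + sum_j [ J_j J_j'/V_j + 0.5 * Vp_j Vp_j'/V_j^2 ],
// with Vp = dV/deta = 2*sp2*f*J; a finite-difference hessian of g is
// available as an option (hess_mode = 1).

static const int MAXETA = 4;

struct EtaCtx {
  const double *t;
  const double *y;
  int nobs;
  const double *dstart;
  const double *damt;
  const double *ddur;
  int ndose;
  double tv[4];          // typical CL, V1, V2, Q
  int eta_idx[4];        // structural param -> eta position, -1 = none
  int d;                 // eta dimension
  double oinv[MAXETA * MAXETA];
  double ologdet;
  double sp2, sa2;
  double floor_v;
};

static void predict_eta(const EtaCtx &c, const double *eta, double *f) {
  double par[4];
  for (int p = 0; p < 4; ++p) {
    par[p] = c.tv[p];
    if (c.eta_idx[p] >= 0) par[p] *= std::exp(eta[c.eta_idx[p]]);
  }
  Macro m = macro_coefs(par[0], par[1], par[2], par[3]);
  for (int i = 0; i < c.nobs; ++i) {
    double acc = 0.0;
    for (int dd = 0; dd < c.ndose; ++dd) {
      double s = c.t[i] - c.dstart[dd];
      if (s <= 0.0) continue;
      acc += conc_one(m, c.damt[dd] / c.ddur[dd], c.ddur[dd], s);
    }
    f[i] = acc;
  }
}

static double g_of_eta(const EtaCtx &c, const double *eta, const double *f) {
  double quad = 0.0;
  for (int i = 0; i < c.d; ++i)
    for (int j = 0; j < c.d; ++j)
      quad += eta[i] * c.oinv[i * c.d + j] * eta[j];
  double out = c.d * std::log(2.0 * M_PI) + c.ologdet + quad;
  for (int j = 0; j < c.nobs; ++j) {
    double v = c.sp2 * f[j] * f[j] + c.sa2;
    if (v < c.floor_v) v = c.floor_v;
    double r = c.y[j] - f[j];
    out += std::log(2.0 * M_PI * v) + r * r / v;
  }
  return out;
}

static double g_at(const EtaCtx &c, const double *eta, std::vector<double> &buf) {
  predict_eta(c, eta, buf.data());
  return g_of_eta(c, eta, buf.data());
}

// cholesky of d x d (row-major), returns false if not PD; logdet accumulated
static bool chol_small(double *a, int d, double &logdet) {
  logdet = 0.0;
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = a[i * d + j];
      for (int k = 0; k < j; ++k) s -= a[i * d + k] * a[j * d + k];
      if (i == j) {
        if (s <= 0.0) return false;
        a[i * d + i] = std::sqrt(s);
        logdet += 2.0 * std::log(a[i * d + i]);
      } else {
        a[i * d + j] = s / a[j * d + j];
      }
    }
    for (int j = i + 1; j < d; ++j) a[i * d + j] = 0.0;
  }
  return true;
}

static void chol_solve(const double *l, int d, const double *b, double *x) {
  // solve L L' x = b
  double ytmp[MAXETA];
  for (int i = 0; i < d; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= l[i * d + k] * ytmp[k];
    ytmp[i] = s / l[i * d + i];
  }
  for (int i = d - 1; i >= 0; --i) {
    double s = ytmp[i];
    for (int k = i + 1; k < d; ++k) s -= l[k * d + i] * x[k];
    x[i] = s / l[i * d + i];
  }
}

// gradient of g/2 and GN hessian of g/2 at eta; J by forward differences
// (reuses the profile already computed at eta; J precision only moves the
// inner mode by O(h), which perturbs the OFV at second order)
static void grad_hess(const EtaCtx &c, const double *eta, const double *f,
                      double *grad, double *hess,
                      std::vector<double> &fp, std::vector<double> &fm,
                      std::vector<double> &jac) {
  int d = c.d, n = c.nobs;
  const double h = 1e-6;
  double ep[MAXETA];
  (void)fm;
  for (int k = 0; k < d; ++k) {
    for (int i = 0; i < d; ++i) ep[i] = eta[i];
    ep[k] = eta[k] + h;
    predict_eta(c, ep, fp.data());
    for (int j = 0; j < n; ++j) jac[j * d + k] = (fp[j] - f[j]) / h;
  }
  for (int i = 0; i < d; ++i) {
    grad[i] = 0.0;
    for (int j = 0; j < d; ++j) {
      grad[i] += c.oinv[i * d + j] * eta[j];
      hess[i * d + j] = c.oinv[i * d + j];
    }
  }
  for (int j = 0; j < n; ++j) {
    double v = c.sp2 * f[j] * f[j] + c.sa2;
    if (v < c.floor_v) v = c.floor_v;
    double r = c.y[j] - f[j];
    double vfac = 0.5 * (1.0 / v - r * r / (v * v));
    for (int i = 0; i < d; ++i) {
      double Ji = jac[j * d + i];
      double Vpi = 2.0 * c.sp2 * f[j] * Ji;
      grad[i] += -r * Ji / v + vfac * Vpi;
      for (int k = 0; k <= i; ++k) {
        double Jk = jac[j * d + k];
        double Vpk = 2.0 * c.sp2 * f[j] * Jk;
        double add = Ji * Jk / v + 0.5 * Vpi * Vpk / (v * v);
        hess[i * d + k] += add;
        if (k < i) hess[k * d + i] += add;
      }
    }
  }
}

// Newton inner optimization; returns convergence flag
static bool solve_eta(const EtaCtx &c, double *eta, double &gval,
                      double *hess_out, int max_iter, double tol) {
  int d = c.d;
  std::vector<double> f(c.nobs), fp(c.nobs), fm(c.nobs), jac((size_t)c.nobs * d);
  double grad[MAXETA], hess[MAXETA * MAXETA], lmat[MAXETA * MAXETA];
  double step[MAXETA], etry[MAXETA];
  std::vector<double> ftry(c.nobs);
  predict_eta(c, eta, f.data());
  gval = g_of_eta(c, eta, f.data());
  bool conv = false;
  for (int it = 0; it < max_iter; ++it) {
    grad_hess(c, eta, f.data(), grad, hess, fp, fm, jac);
    double gn = 0.0;
    for (int i = 0; i < d; ++i) gn = std::max(gn, std::fabs(grad[i]));
    if (gn < tol) { conv = true; break; }
    for (int i = 0; i < d * d; ++i) lmat[i] = hess[i];
    double ld;
    if (!chol_small(lmat, d, ld)) {
      // ridge fallback
      for (int i = 0; i < d * d; ++i) lmat[i] = hess[i];
      for (int i = 0; i < d; ++i) lmat[i * d + i] += 1e-4 + gn;
      if (!chol_small(lmat, d, ld)) break;
    }
    double ng[MAXETA];
    for (int i = 0; i < d; ++i) ng[i] = -grad[i];
    chol_solve(lmat, d, ng, step);
    double alpha = 1.0;
    bool moved = false;
    for (int ls = 0; ls < 25; ++ls) {
      for (int i = 0; i < d; ++i) etry[i] = eta[i] + alpha * step[i];
      predict_eta(c, etry, ftry.data());
      double gtry = g_of_eta(c, etry, ftry.data());
      if (gtry < gval) {
        for (int i = 0; i < d; ++i) eta[i] = etry[i];
        std::copy(ftry.begin(), ftry.end(), f.begin());
        gval = gtry;
        moved = true;
        break;
      }
      alpha *= 0.5;
    }
    if (!moved) {
      // gradient already could not be reduced; accept if small enough
      conv = gn < 1e-3;
      break;
    }
  }
  // final GN hessian at the mode for the Laplace determinant
  grad_hess(c, eta, f.data(), grad, hess, fp, fm, jac);
  for (int i = 0; i < d * d; ++i) hess_out[i] = hess[i];
  return conv;
}

static double laplace_logdet(const EtaCtx &c, double *eta, const double *hess_gn,
                             int hess_mode, std::vector<double> &buf) {
  int d = c.d;
  double hmat[MAXETA * MAXETA];
  if (hess_mode == 1) {
    // finite-difference hessian of g/2
    const double h = 1e-3;
    double e0 = g_at(c, eta, buf);
    double ep[MAXETA];
    for (int i = 0; i < d; ++i) {
      for (int k = 0; k < d; ++k) ep[k] = eta[k];
      ep[i] = eta[i] + h;
      double gp = g_at(c, ep, buf);
      ep[i] = eta[i] - h;
      double gm = g_at(c, ep, buf);
      hmat[i * d + i] = 0.5 * (gp - 2.0 * e0 + gm) / (h * h);
      for (int j = 0; j < i; ++j) {
        for (int k = 0; k < d; ++k) ep[k] = eta[k];
        ep[i] = eta[i] + h; ep[j] = eta[j] + h;
        double gpp = g_at(c, ep, buf);
        ep[j] = eta[j] - h;
        double gpm = g_at(c, ep, buf);
        ep[i] = eta[i] - h; ep[j] = eta[j] + h;
        double gmp = g_at(c, ep, buf);
        ep[j] = eta[j] - h;
        double gmm = g_at(c, ep, buf);
        double v = 0.5 * (gpp - gpm - gmp + gmm) / (4.0 * h * h);
        hmat[i * d + j] = v;
        hmat[j * d + i] = v;
      }
    }
    double ld;
    double tmp[MAXETA * MAXETA];
    std::copy(hmat, hmat + d * d, tmp);
    if (chol_small(tmp, d, ld)) return ld;
    // fall through to GN if numeric hessian is not PD
  }
  double tmp[MAXETA * MAXETA];
  std::copy(hess_gn, hess_gn + d * d, tmp);
  double ld;
  if (!chol_small(tmp, d, ld)) {
    std::copy(hess_gn, hess_gn + d * d, tmp);
    for (int i = 0; i < d; ++i) tmp[i * d + i] += 1e-8;
    if (!chol_small(tmp, d, ld)) return R_PosInf;
  }
  return ld;
}

static void fill_ctx_omega(EtaCtx &c, const NumericMatrix &omega) {
  int d = omega.nrow();
  c.d = d;
  double l[MAXETA * MAXETA];
  for (int i = 0; i < d; ++i)
    for (int j = 0; j < d; ++j) l[i * d + j] = omega(i, j);
  double ld;
  if (!chol_small(l, d, ld)) stop("Omega is not positive definite");
  c.ologdet = ld;
  // invert via cholesky solves of unit vectors
  double e[MAXETA], x[MAXETA];
  for (int j = 0; j < d; ++j) {
    for (int i = 0; i < d; ++i) e[i] = (i == j) ? 1.0 : 0.0;
    chol_solve(l, d, e, x);
    for (int i = 0; i < d; ++i) c.oinv[i * d + j] = x[i];
  }
}

static EtaCtx make_ctx(const List &subj, const NumericMatrix &tvrow_m, int si,
                       const IntegerVector &eta_idx, const NumericMatrix &omega,
                       double sp2, double sa2) {
  EtaCtx c;
  NumericVector t = subj["t"], y = subj["y"], ds = subj["dstart"],
                da = subj["damt"], du = subj["ddur"];
  c.t = REAL(t); c.y = REAL(y); c.nobs = t.size();
  c.dstart = REAL(ds); c.damt = REAL(da); c.ddur = REAL(du);
  c.ndose = ds.size();
  for (int p = 0; p < 4; ++p) {
    c.tv[p] = tvrow_m(si, p);
    c.eta_idx[p] = eta_idx[p];
  }
  fill_ctx_omega(c, omega);
  c.sp2 = sp2; c.sa2 = sa2;
  c.floor_v = 1e-12;
  return c;
}

// [[Rcpp::export]]
List cpp_map_eta(List subj, NumericMatrix tv, int si, IntegerVector eta_idx,
                 NumericMatrix omega, double sp2, double sa2,
                 NumericVector eta0, int max_iter, double tol) {
  EtaCtx c = make_ctx(subj, tv, si, eta_idx, omega, sp2, sa2);
  double eta[MAXETA] = {0, 0, 0, 0};
  for (int i = 0; i < c.d; ++i) eta[i] = eta0[i];
  double gval, hess[MAXETA * MAXETA];
  bool conv = solve_eta(c, eta, gval, hess, max_iter, tol);
  if (!conv) {
    // fallback: restart from zero, then keep the better of the two
    double eta2[MAXETA] = {0, 0, 0, 0};
    double g2, h2[MAXETA * MAXETA];
    bool conv2 = solve_eta(c, eta2, g2, h2, max_iter, tol);
    if (g2 < gval || conv2) {
      for (int i = 0; i < c.d; ++i) eta[i] = eta2[i];
      gval = g2;
      std::copy(h2, h2 + MAXETA * MAXETA, hess);
      conv = conv2;
    }
  }
  NumericVector etaout(c.d);
  NumericMatrix hout(c.d, c.d);
  for (int i = 0; i < c.d; ++i) {
    etaout[i] = eta[i];
    for (int j = 0; j < c.d; ++j) hout(i, j) = hess[i * c.d + j];
  }
  return List::create(_["eta"] = etaout, _["g"] = gval, _["converged"] = conv,
                      _["hessian"] = hout);
}

// [[Rcpp::export]]
List cpp_foce_ofv(List subjects, NumericMatrix tv, IntegerVector eta_idx,
                  NumericMatrix omega, double sp2, double sa2,
                  NumericMatrix eta_warm, int hess_mode, int max_iter,
                  double tol) {
  int n = subjects.size();
  int d = omega.nrow();
  double ofv = 0.0;
  NumericMatrix etas(n, d);
  NumericVector ll(n);
  LogicalVector conv(n);
  std::vector<double> buf;
  for (int s = 0; s < n; ++s) {
    List subj = subjects[s];
    EtaCtx c = make_ctx(subj, tv, s, eta_idx, omega, sp2, sa2);
    if (c.nobs == 0) { conv[s] = true; continue; }
    if ((int)buf.size() < c.nobs) buf.resize(c.nobs);
    double eta[MAXETA];
    for (int i = 0; i < d; ++i) eta[i] = eta_warm(s, i);
    double gval, hess[MAXETA * MAXETA];
    bool ok = solve_eta(c, eta, gval, hess, max_iter, tol);
    if (!ok) {
      double eta2[MAXETA] = {0, 0, 0, 0};
      double g2, h2[MAXETA * MAXETA];
      bool ok2 = solve_eta(c, eta2, g2, h2, max_iter, tol);
      if (g2 < gval || ok2) {
        for (int i = 0; i < d; ++i) eta[i] = eta2[i];
        gval = g2;
        std::copy(h2, h2 + MAXETA * MAXETA, hess);
        ok = ok2;
      }
    }
    double ld = laplace_logdet(c, eta, hess, hess_mode, buf);
    double m2ll = gval - d * std::log(2.0 * M_PI) + ld;
    ll[s] = m2ll;
    ofv += m2ll;
    conv[s] = ok;
    for (int i = 0; i < d; ++i) etas(s, i) = eta[i];
  }
  return List::create(_["ofv"] = ofv, _["etas"] = etas, _["ll"] = ll,
                      _["converged"] = conv);
}
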