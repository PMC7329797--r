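// FOCE-with-interaction (Laplacian-at-the-mode) likelihood core.
//
// The inner problem -- the conditional mode of the log-scale random effects
// eta for one subject -- is solved by Newton iteration with an Armijo line
// search.  Gradients of the penalized deviance g(eta) are computed by the
// complex-step method (machine precision, one evaluation per dimension);
// the Newton Hessian is a central difference of those gradients.  The
// subject contribution to the objective function value is the Laplace
// approximation  OFV_i = g(eta_hat) - k*log(2*pi) + log det H,  where H is
// the Hessian of g/2 at the mode, so that OFV = -2 log L including all
// normalizing constants (tests compare it against adaptive quadrature).
#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::complex<double> cplx;

static const double TWO_PI = 6.283185307179586476925286766559;

// Central-compartment concentration at time tt for a superposition of
// zero-order infusions.  Templated so it can be evaluated with complex
// parameters for complex-step differentiation.  During-infusion and
// post-infusion branches collapse to one expression via
// u = min(s, D), v = max(s - D, 0) with s the time since infusion start.
template <typename T>
T conc_at(double tt, int nd, const double* ds, const double* dd,
          const double* dr, const T& V1, const T& CL, const T& Q,
          const T& V2, int ncomp) {
  T out(0.0);
  if (ncomp == 1) {
    T k = CL / V1;
    for (int d = 0; d < nd; ++d) {
      double s = tt - ds[d];
      if (s <= 0.0) continue;
      double u = s < dd[d] ? s : dd[d];
      double v = s > dd[d] ? s - dd[d] : 0.0;
      out += (dr[d] / CL) * (1.0 - exp(-k * u)) * exp(-k * v);
    }
    return out;
  }
  T k10 = CL / V1, k12 = Q / V1, k21 = Q / V2;
  T sum = k10 + k12 + k21;
  T disc = sqrt(sum * sum - 4.0 * k10 * k21);  // > 0 strictly for k12 > 0
  T a = (sum + disc) / 2.0;
  T b = (sum - disc) / 2.0;
  T A = (a - k21) / disc;
  T B = (k21 - b) / disc;
  for (int d = 0; d < nd; ++d) {
    double s = tt - ds[d];
    if (s <= 0.0) continue;
    double u = s < dd[d] ? s : dd[d];
    double v = s > dd[d] ? s - dd[d] : 0.0;
    out += (dr[d] / V1) * ((A / a) * (1.0 - exp(-a * u)) * exp(-a * v) +
                           (B / b) * (1.0 - exp(-b * u)) * exp(-b * v));
  }
  return out;
}

struct SubjData {
  const double* y;
  const double* t;
  int ny;
  const double* ds;
  const double* dd;
  const double* dr;
  int nd;
  double typ[4];  // typical individual params V1, CL, Q, V2 (covariates in)
  int ncomp;
  const int* map;  // eta slot -> param index
  int k;
  const double* omega2;
  double sa2, sp2;
};

// Penalized deviance g(eta) = -2 log p(y | eta) - 2 log p(eta).
template <typename T>
T gval(const SubjData& S, const std::vector<T>& eta) {
  T p[4];
  for (int j = 0; j < 4; ++j) p[j] = T(S.typ[j]);
  for (int m = 0; m < S.k; ++m) p[S.map[m]] *= exp(eta[m]);
  T g(0.0);
  for (int j = 0; j < S.ny; ++j) {
    T f = conc_at(S.t[j], S.nd, S.ds, S.dd, S.dr, p[0], p[1], p[2], p[3],
                  S.ncomp);
    T v = S.sa2 + S.sp2 * f * f;  // interaction: variance at conditional pred
    T r = S.y[j] - f;
    g += log(TWO_PI * v) + r * r / v;
  }
  for (int m = 0; m < S.k; ++m)
    g += eta[m] * eta[m] / S.omega2[m] + log(TWO_PI * S.omega2[m]);
  return g;
}

static double greal(const SubjData& S, const std::vector<double>& eta) {
  return gval<double>(S, eta);
}

// Complex-step gradient: exact to machine precision.
static void ggrad(const SubjData& S, const std::vector<double>& eta,
                  std::vector<double>& grad) {
  const double h = 1e-20;
  std::vector<cplx> ec(S.k);
  for (int m = 0; m < S.k; ++m) ec[m] = cplx(eta[m], 0.0);
  for (int m = 0; m < S.k; ++m) {
    ec[m] = cplx(eta[m], h);
    grad[m] = gval<cplx>(S, ec).imag() / h;
    ec[m] = cplx(eta[m], 0.0);
  }
}

// Hessian of g by central differences of the complex-step gradient.
static void ghess(const SubjData& S, const std::vector<double>& eta,
                  std::vector<double>& H) {
  int k = S.k;
  std::vector<double> e(eta), gp(k), gm(k);
  for (int m = 0; m < k; ++m) {
    double d = 1e-4 * std::max(1.0, std::fabs(eta[m]));
    e[m] = eta[m] + d;
    ggrad(S, e, gp);
    e[m] = eta[m] - d;
    ggrad(S, e, gm);
    e[m] = eta[m];
    for (int n = 0; n < k; ++n) H[m * k + n] = (gp[n] - gm[n]) / (2.0 * d);
  }
  for (int m = 0; m < k; ++m)  // symmetrize
    for (int n = m + 1; n < k; ++n) {
      double v = 0.5 * (H[m * k + n] + H[n * k + m]);
      H[m * k + n] = H[n * k + m] = v;
    }
}

// Dense Cholesky for the (at most 4 x 4) eta problem.
static bool cholesky(int k, const std::vector<double>& A,
                     std::vector<double>& L) {
  for (int i = 0; i < k * k; ++i) L[i] = 0.0;
  for (int i = 0; i < k; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * k + j];
      for (int m = 0; m < j; ++m) s -= L[i * k + m] * L[j * k + m];
      if (i == j) {
        if (s <= 0.0 || !std::isfinite(s)) return false;
        L[i * k + i] = std::sqrt(s);
      } else {
        L[i * k + j] = s / L[j * k + j];
      }
    }
  }
  return true;
}

static void chol_solve(int k, const std::vector<double>& L,
                       const std::vector<double>& b, std::vector<double>& x) {
  std::vector<double> z(k);
  for (int i = 0; i < k; ++i) {
    double s = b[i];
    for (int m = 0; m < i; ++m) s -= L[i * k + m] * z[m];
    z[i] = s / L[i * k + i];
  }
  for (int i = k - 1; i >= 0; --i) {
    double s = z[i];
    for (int m = i + 1; m < k; ++m) s -= L[m * k + i] * x[m];
    x[i] = s / L[i * k + i];
  }
}

// Newton search for the conditional mode of eta; returns convergence flag.
static bool inner_newton(const SubjData& S, std::vector<double>& eta,
                         double& gmin, int max_iter, double grad_tol) {
  int k = S.k;
  if (k == 0) {
    gmin = greal(S, eta);
    return true;
  }
  std::vector<double> grad(k), H(k * k), L(k * k), step(k), negg(k),
      trial(k);
  gmin = greal(S, eta);
  if (!std::isfinite(gmin)) {  // restart from the prior mean
    std::fill(eta.begin(), eta.end(), 0.0);
    gmin = greal(S, eta);
    if (!std::isfinite(gmin)) return false;
  }
  for (int it = 0; it < max_iter; ++it) {
    ggrad(S, eta, grad);
    double gn = 0.0;
    for (int m = 0; m < k; ++m) gn = std::max(gn, std::fabs(grad[m]));
    if (gn < grad_tol) return true;
    ghess(S, eta, H);
    double lam = 0.0;
    std::vector<double> Hreg(H);
    while (!cholesky(k, Hreg, L)) {
      lam = lam == 0.0 ? 1e-6 : lam * 10.0;
      if (lam > 1e10) return false;
      Hreg = H;
      for (int m = 0; m < k; ++m) Hreg[m * k + m] += lam;
    }
    for (int m = 0; m < k; ++m) negg[m] = -grad[m];
    chol_solve(k, L, negg, step);
    double slope = 0.0;
    for (int m = 0; m < k; ++m) slope += grad[m] * step[m];
    double alpha = 1.0;
    bool moved = false;
    for (int ls = 0; ls < 40; ++ls) {
      for (int m = 0; m < k; ++m) trial[m] = eta[m] + alpha * step[m];
      double gt = greal(S, trial);
      if (std::isfinite(gt) && gt <= gmin + 1e-4 * alpha * slope) {
        eta = trial;
        gmin = gt;
        moved = true;
        break;
      }
      alpha *= 0.5;
    }
    if (!moved) {  // stagnation: accept current point if gradient is small
      return gn < 1e-4;
    }
  }
  ggrad(S, eta, grad);
  double gn = 0.0;
  for (int m = 0; m < k; ++m) gn = std::max(gn, std::fabs(grad[m]));
  return gn < 1e-4;
}

static SubjData make_subj(int i, const NumericVector& y,
                          const NumericVector& t, const IntegerVector& ostart,
                          const NumericVector& ds, const NumericVector& dd,
                          const NumericVector& dr, const IntegerVector& dstart,
                          const NumericMatrix& typ, int ncomp,
                          const IntegerVector& eta_map,
                          const NumericVector& omega2, double sigma_add,
                          double sigma_prop, std::vector<int>& map_buf) {
  SubjData S;
  S.y = &y[0] + ostart[i];
  S.t = &t[0] + ostart[i];
  S.ny = ostart[i + 1] - ostart[i];
  S.ds = &ds[0] + dstart[i];
  S.dd = &dd[0] + dstart[i];
  S.dr = &dr[0] + dstart[i];
  S.nd = dstart[i + 1] - dstart[i];
  for (int j = 0; j < 4; ++j)
    S.typ[j] = j < typ.ncol() ? typ(i, j) : 0.0;
  S.ncomp = ncomp;
  S.k = eta_map.size();
  map_buf.resize(S.k);
  for (int m = 0; m < S.k; ++m) map_buf[m] = eta_map[m];
  S.map = map_buf.data();
  S.omega2 = S.k > 0 ? &omega2[0] : NULL;
  S.sa2 = sigma_add * sigma_add;
  S.sp2 = sigma_prop * sigma_prop;
  return S;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_foce_ofv")]]
List cpp_foce_ofv(NumericVector y, NumericVector t, IntegerVector ostart,
                  NumericVector ds, NumericVector dd, NumericVector dr,
                  IntegerVector dstart, NumericMatrix typ, int ncomp,
                  IntegerVector eta_map, NumericVector omega2,
                  double sigma_add, double sigma_prop,
                  NumericMatrix eta_start, int max_iter, double grad_tol,
                  bool want_hessian) {
  int n = typ.nrow();
  int k = eta_map.size();
  NumericVector ofv_i(n);
  NumericMatrix eta_out(n, k);
  LogicalVector conv(n);
  NumericVector hess_out(want_hessian ? n * k * k : 0);
  double total = 0.0;
  bool ok = true;
  std::vector<int> map_buf;
  for (int i = 0; i < n; ++i) {
    SubjData S = make_subj(i, y, t, ostart, ds, dd, dr, dstart, typ, ncomp,
                           eta_map, omega2, sigma_add, sigma_prop, map_buf);
    std::vector<double> eta(k);
    for (int m = 0; m < k; ++m) eta[m] = eta_start(i, m);
    double gmin;
    bool c = inner_newton(S, eta, gmin, max_iter, grad_tol);
    conv[i] = c;
    double li = NA_REAL;
    if (c && S.ny > 0 && k > 0) {
      std::vector<double> H(k * k), L(k * k);
      ghess(S, eta, H);
      for (int m = 0; m < k * k; ++m) H[m] *= 0.5;  // Hessian of g/2
      double lam = 0.0;
      std::vector<double> Hreg(H);
      while (!cholesky(k, Hreg, L)) {
        lam = lam == 0.0 ? 1e-10 : lam * 10.0;
        if (lam > 1.0) break;
        Hreg = H;
        for (int m = 0; m < k; ++m) Hreg[m * k + m] += lam;
      }
      double logdet = 0.0;
      for (int m = 0; m < k; ++m) logdet += 2.0 * std::log(L[m * k + m]);
      li = gmin - k * std::log(TWO_PI) + logdet;
      if (want_hessian)
        for (int m = 0; m < k * k; ++m) hess_out[(size_t)i * k * k + m] = H[m];
    } else if (c) {
      li = gmin;
    }
    if (!std::isfinite(li)) {
      ok = false;
      li = NA_REAL;
    } else {
      total += li;
    }
    ofv_i[i] = li;
    for (int m = 0; m < k; ++m) eta_out(i, m) = eta[m];
  }
  return List::create(_["ofv"] = ok ? total : NA_REAL, _["ofv_i"] = ofv_i,
                      _["eta"] = eta_out, _["converged"] = conv,
                      _["hessians"] = hess_out, _["ok"] = ok);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_conc_profile")]]
NumericVector cpp_conc_profile(NumericVector times, NumericVector ds,
                               NumericVector dd, NumericVector dr,
                               NumericVector pars, int ncomp) {
  int nt = times.size();
  NumericVector out(nt);
  double V1 = pars[0], CL = pars[1];
  double Q = pars.size() > 2 ? pars[2] : 0.0;
  double V2 = pars.size() > 3 ? pars[3] : 1.0;
  for (int j = 0; j < nt; ++j)
    out[j] = conc_at<double>(times[j], ds.size(), &ds[0], &dd[0], &dr[0], V1,
                             CL, Q, V2, ncomp);
  return out;
}
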