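// Core ODE machinery for the branched hematopoietic lineage model.
//
// State layouts:
//   normal system:  y = (S, P, TDl, TDm)
//   dual system:    y = (S, P, TDl, TDm, SL, PL, TDlL, TDmL)
// Parameter vector layout (normal or leukemic lineage), length 12:
//   [0] p0_max  [1] p1_max  [2] q1_max  [3] eta1_max  [4] eta2_max
//   [5] d_l     [6] d_m     [7] g1      [8] g2        [9] g3
//   [10] g4     [11] g5
// Feedback assignments (regulators are total populations, normal +
// leukemic). g1 acts per cell; g2..g5 act on populations normalized by
// the characteristic marrow scale N0 = 1e5 cells:
//   p0  = p0_max  / (1 + g1 * P_tot + delta)
//   eta1= eta1_max/ (1 + g2 * S_tot / N0)    (eta1_max scaled by the TKI
//                                             division factor for the
//                                             leukemic lineage under therapy)
//   p1  = p1_max  / (1 + g3 * TDm_tot / N0)
//   q1  = q1_max  / (1 + g4 * TDm_tot / N0)
//   eta2= eta2_max/ (1 + g5 * S_tot / N0)
// Therapy vector, length 4: [kill_S, kill_P, division_factor, delta].

#include <RcppArmadillo.h>
using namespace Rcpp;

static const double ATOL = 1e-3;   // cells
static const double N0 = 1e5;      // normalization scale for g2..g5

struct Rates {
  double p0, p1, q1, eta1, eta2;
};

static inline Rates eff_rates(const double* par, double Stot, double Ptot,
                              double TDmtot, double delta,
                              double divfac = 1.0) {
  Rates r;
  r.p0   = par[0] / (1.0 + par[7] * Ptot + delta);
  r.eta1 = par[3] * divfac / (1.0 + par[8] * Stot / N0);
  r.p1   = par[1] / (1.0 + par[9] * TDmtot / N0);
  r.q1   = par[2] / (1.0 + par[10] * TDmtot / N0);
  r.eta2 = par[4] / (1.0 + par[11] * Stot / N0);
  return r;
}

static inline void rhs_normal_c(const double* y, const double* par,
                                double delta, double* dy) {
  Rates r = eff_rates(par, y[0], y[1], y[3], delta);
  dy[0] = (2.0 * r.p0 - 1.0) * r.eta1 * y[0];
  dy[1] = 2.0 * (1.0 - r.p0) * r.eta1 * y[0] + (2.0 * r.p1 - 1.0) * r.eta2 * y[1];
  dy[2] = 2.0 * r.q1 * r.eta2 * y[1] - par[5] * y[2];
  dy[3] = 2.0 * (1.0 - r.p1 - r.q1) * r.eta2 * y[1] - par[6] * y[3];
}

// Dual lineage: both lineages sense the summed regulator populations.
static inline void rhs_dual_c(const double* y, const double* parN,
                              const double* parL, const double* ther,
                              double* dy) {
  double Stot = y[0] + y[4], Ptot = y[1] + y[5], TDmtot = y[3] + y[7];
  double killS = ther[0], killP = ther[1], divfac = ther[2], delta = ther[3];
  Rates rn = eff_rates(parN, Stot, Ptot, TDmtot, delta);
  Rates rl = eff_rates(parL, Stot, Ptot, TDmtot, delta, divfac);
  dy[0] = (2.0 * rn.p0 - 1.0) * rn.eta1 * y[0];
  dy[1] = 2.0 * (1.0 - rn.p0) * rn.eta1 * y[0] + (2.0 * rn.p1 - 1.0) * rn.eta2 * y[1];
  dy[2] = 2.0 * rn.q1 * rn.eta2 * y[1] - parN[5] * y[2];
  dy[3] = 2.0 * (1.0 - rn.p1 - rn.q1) * rn.eta2 * y[1] - parN[6] * y[3];
  dy[4] = (2.0 * rl.p0 - 1.0) * rl.eta1 * y[4] - killS * rl.eta1 * y[4];
  dy[5] = 2.0 * (1.0 - rl.p0) * rl.eta1 * y[4] + (2.0 * rl.p1 - 1.0) * rl.eta2 * y[5]
          - killP * rl.eta2 * y[5];
  dy[6] = 2.0 * rl.q1 * rl.eta2 * y[5] - parL[5] * y[6];
  dy[7] = 2.0 * (1.0 - rl.p1 - rl.q1) * rl.eta2 * y[5] - parL[6] * y[7];
}

// ---------------------------------------------------------------------------
// Dormand-Prince 5(4) with adaptive step, stepping exactly onto output times.
// ---------------------------------------------------------------------------

typedef void (*RhsFun)(const double* y, void* ctx, double* dy);

struct NormalCtx { const double* par; double delta; };
struct DualCtx { const double* parN; const double* parL; const double* ther; };

static void rhs_normal_wrap(const double* y, void* ctx, double* dy) {
  NormalCtx* c = (NormalCtx*)ctx;
  rhs_normal_c(y, c->par, c->delta, dy);
}
static void rhs_dual_wrap(const double* y, void* ctx, double* dy) {
  DualCtx* c = (DualCtx*)ctx;
  rhs_dual_c(y, c->parN, c->parL, c->ther, dy);
}

// Butcher tableau (Dormand-Prince)
static const double dp_c[7] = {0., 1./5, 3./10, 4./5, 8./9, 1., 1.};
static const double dp_a[7][6] = {
  {0,0,0,0,0,0},
  {1./5,0,0,0,0,0},
  {3./40, 9./40,0,0,0,0},
  {44./45, -56./15, 32./9,0,0,0},
  {19372./6561, -25360./2187, 64448./6561, -212./729,0,0},
  {9017./3168, -355./33, 46732./5247, 49./176, -5103./18656,0},
  {35./384, 0., 500./1113, 125./192, -2187./6784, 11./84}};
static const double dp_b5[7] = {35./384, 0., 500./1113, 125./192,
                                -2187./6784, 11./84, 0.};
static const double dp_b4[7] = {5179./57600, 0., 7571./16695, 393./640,
                                -92097./339200, 187./2100, 1./40};

// Integrate from t0 to t1, overwriting y. Returns false on failure.
static bool dp_integrate(RhsFun f, void* ctx, int n, double* y,
                         double t0, double t1, double* h_inout,
                         double rtol = 1e-8, double atol = ATOL) {
  if (t1 <= t0) return true;
  std::vector<double> k(7 * n), ytmp(n), y5(n), y4(n);
  double t = t0;
  double h = *h_inout;
  if (h <= 0.0 || h > (t1 - t0)) h = std::min(1.0, t1 - t0);
  int nstep = 0;
  const int MAXSTEP = 2000000;
  while (t < t1) {
    if (++nstep > MAXSTEP) return false;
    if (t + h > t1) h = t1 - t;
    // stages
    f(y, ctx, &k[0]);
    for (int s = 1; s < 7; ++s) {
      for (int i = 0; i < n; ++i) {
        double acc = y[i];
        for (int j = 0; j < s; ++j) acc += h * dp_a[s][j] * k[j * n + i];
        ytmp[i] = acc;
      }
      f(&ytmp[0], ctx, &k[s * n]);
    }
    double errnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      double s5 = y[i], s4 = y[i];
      for (int s = 0; s < 7; ++s) {
        s5 += h * dp_b5[s] * k[s * n + i];
        s4 += h * dp_b4[s] * k[s * n + i];
      }
      y5[i] = s5; y4[i] = s4;
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(s5));
      double e = (s5 - s4) / sc;
      errnorm += e * e;
    }
    errnorm = std::sqrt(errnorm / n);
    if (!std::isfinite(errnorm)) { h *= 0.25; if (h < 1e-14) return false; continue; }
    if (errnorm <= 1.0) {
      t += h;
      for (int i = 0; i < n; ++i) {
        double v = y5[i];
        if (v < 0.0) {
          if (v > -1e3 * ATOL) v = 0.0; else return false;
        }
        // demographic extinction: a declining compartment below one cell
        // dies out (influx-fed compartments can regrow from zero)
        if (v < 1.0 && v < y[i]) v = 0.0;
        y[i] = v;
      }
    }
    double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h < 1e-12) return false;
  }
  *h_inout = h;
  return true;
}

static NumericMatrix integrate_at_times(RhsFun f, void* ctx, int n,
                                        NumericVector y0, NumericVector times,
                                        double rtol = 1e-8,
                                        double atol = ATOL) {
  int m = times.size();
  NumericMatrix out(m, n);
  std::vector<double> y(y0.begin(), y0.end());
  double t = times[0];
  double h = 0.1;
  for (int i = 0; i < n; ++i) out(0, i) = y[i];
  for (int r = 1; r < m; ++r) {
    if (!(times[r] > times[r - 1]))
      stop("output times must be strictly increasing");
    if (!dp_integrate(f, ctx, n, &y[0], t, times[r], &h, rtol, atol))
      stop("ODE solver failure near t = %f", t);
    t = times[r];
    for (int i = 0; i < n; ++i) out(r, i) = y[i];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_integrate_normal(NumericVector y0, NumericVector par,
                                   NumericVector times, double delta = 0.0,
                                   double rtol = 1e-8, double atol = 1e-3) {
  if (y0.size() != 4 || par.size() != 12) stop("bad dimensions");
  NormalCtx ctx{REAL(par), delta};
  return integrate_at_times(rhs_normal_wrap, &ctx, 4, y0, times, rtol, atol);
}

// [[Rcpp::export]]
NumericMatrix cpp_integrate_dual(NumericVector y0, NumericVector parN,
                                 NumericVector parL, NumericVector times,
                                 NumericVector therapy,
                                 double rtol = 1e-8, double atol = 1e-3) {
  if (y0.size() != 8 || parN.size() != 12 || parL.size() != 12 ||
      therapy.size() != 4) stop("bad dimensions");
  DualCtx ctx{REAL(parN), REAL(parL), REAL(therapy)};
  return integrate_at_times(rhs_dual_wrap, &ctx, 8, y0, times, rtol, atol);
}

// Relative derivative norm used as the steady-state criterion.
static double deriv_norm(RhsFun f, void* ctx, int n, const double* y) {
  std::vector<double> dy(n);
  f(y, ctx, &dy[0]);
  double m = 0.0;
  for (int i = 0; i < n; ++i)
    m = std::max(m, std::fabs(dy[i]) / (1.0 + std::fabs(y[i])));
  return m;
}

static List steady_generic(RhsFun f, void* ctx, int n, NumericVector y0,
                           double tol, double window, double tmax) {
  std::vector<double> y(y0.begin(), y0.end());
  double t = 0.0, h = 0.1;
  bool conv = false;
  while (t < tmax) {
    double tnext = std::min(t + window, tmax);
    if (!dp_integrate(f, ctx, n, &y[0], t, tnext, &h)) {
      return List::create(_["state"] = NumericVector(y.begin(), y.end()),
                          _["converged"] = false, _["t"] = t,
                          _["failed"] = true);
    }
    double d0 = deriv_norm(f, ctx, n, &y[0]);
    t = tnext;
    if (d0 < tol) {
      // must remain below tol across one further window
      std::vector<double> y2 = y;
      double t2next = std::min(t + window, tmax + window);
      if (dp_integrate(f, ctx, n, &y2[0], t, t2next, &h) &&
          deriv_norm(f, ctx, n, &y2[0]) < tol) {
        y = y2; t = t2next; conv = true; break;
      }
    }
  }
  return List::create(_["state"] = NumericVector(y.begin(), y.end()),
                      _["converged"] = conv, _["t"] = t,
                      _["failed"] = false);
}

// [[Rcpp::export]]
List cpp_steady_normal(NumericVector y0, NumericVector par, double tol = 1e-8,
                       double window = 100.0, double tmax = 5000.0) {
  if (y0.size() != 4 || par.size() != 12) stop("bad dimensions");
  NormalCtx ctx{REAL(par), 0.0};
  return steady_generic(rhs_normal_wrap, &ctx, 4, y0, tol, window, tmax);
}

// [[Rcpp::export]]
List cpp_steady_dual(NumericVector y0, NumericVector parN, NumericVector parL,
                     NumericVector therapy, double tol = 1e-8,
                     double window = 100.0, double tmax = 5000.0) {
  DualCtx ctx{REAL(parN), REAL(parL), REAL(therapy)};
  return steady_generic(rhs_dual_wrap, &ctx, 8, y0, tol, window, tmax);
}

// Batched steady-state evaluation for the cohort grid search.
// parmat: n x 12. Returns n x 5 matrix: S, P, TDl, TDm, converged.
// [[Rcpp::export]]
NumericMatrix cpp_steady_batch(NumericMatrix parmat, NumericVector y0,
                               double tol = 1e-8, double window = 100.0,
                               double tmax = 5000.0) {
  int n = parmat.nrow();
  if (parmat.ncol() != 12 || y0.size() != 4) stop("bad dimensions");
  NumericMatrix out(n, 5);
  std::vector<double> par(12);
  for (int r = 0; r < n; ++r) {
    for (int j = 0; j < 12; ++j) par[j] = parmat(r, j);
    NormalCtx ctx{&par[0], 0.0};
    NumericVector y0r = clone(y0);
    List res = steady_generic(rhs_normal_wrap, &ctx, 4, y0r, tol, window, tmax);
    NumericVector st = res["state"];
    bool conv = res["converged"];
    for (int j = 0; j < 4; ++j) out(r, j) = st[j];
    out(r, 4) = conv ? 1.0 : 0.0;
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rhs_normal(NumericVector y, NumericVector par,
                             double delta = 0.0) {
  NumericVector dy(4);
  rhs_normal_c(REAL(y), REAL(par), delta, REAL(dy));
  return dy;
}

// [[Rcpp::export]]
NumericVector cpp_rhs_dual(NumericVector y, NumericVector parN,
                           NumericVector parL, NumericVector therapy) {
  NumericVector dy(8);
  rhs_dual_c(REAL(y), REAL(parN), REAL(parL), REAL(therapy), REAL(dy));
  return dy;
}
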