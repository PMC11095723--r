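// Dormand-Prince 5(4) integration of the substrate-modulated growth ODEs,
// plus the weighted nonlinear-least-squares objective evaluated over a set
// of culture conditions. Kept in C++ because multi-start calibration and
// profile likelihood evaluate the objective O(10^5) times.
//
// State vector y = (n, cg, cl, co):
//   n  cell population (cells/well)
//   cg glucose, cl lactate, co dissolved oxygen (mol m^-3; co is clamped)
//
// Parameter vector theta = (beta, delta, Vg, Ko, Kg, Kl, cbar_g).
// Constants = (Vo, cbar_o, n_max). Vg and Vo are expressed per 1e6 cells
// so that all calibrated parameters live inside the [1e-7, 1e7] hypercube.
//
// Modulating-effect codes per substrate: 0 zero-order, 1 first-order,
// 2 Michaelis-Menten (positive feedback for oxygen/glucose, negative for
// lactate; the sign is fixed by the substrate's position).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double POP_SCALE = 1e6;  // cells per population unit for Vg, Vo

struct Model {
  int k1, k2, k3;                       // effect codes: oxygen, glucose, lactate
  double beta, delta, Vg, Ko, Kg, Kl, cbarg;
  double Vo, cbaro, nmax;
  double lsign;                         // +1: glycolysis produces lactate
};

static inline void rhs(const Model &m, const double *y, double *dy) {
  const double n = y[0], cg = y[1], cl = y[2], co = y[3];
  double f1 = (m.k1 == 0) ? 1.0 : (m.k1 == 1) ? co : co / (co + m.Ko);
  double f2 = (m.k2 == 0) ? 1.0 : (m.k2 == 1) ? cg : cg / (cg + m.Kg);
  double f3 = (m.k3 == 0) ? 1.0 : (m.k3 == 1) ? cl : m.Kl / (cl + m.Kl);
  const double nm = n / POP_SCALE;
  const double Rg = m.Vg * cg / (cg + m.cbarg);          // per population unit
  const double Ro = m.Vo * co / (co + m.cbaro);
  dy[0] = f1 * f2 * f3 * m.beta * n * (1.0 - n / m.nmax) - m.delta * n;
  dy[1] = -nm * Rg;
  dy[2] = m.lsign * (2.0 * nm * Rg - nm * Ro / 3.0);
  dy[3] = 0.0;                                            // oxygen clamp
}

// Dormand-Prince coefficients
static const double C2 = 1.0 / 5, C3 = 3.0 / 10, C4 = 4.0 / 5, C5 = 8.0 / 9;
static const double A21 = 1.0 / 5;
static const double A31 = 3.0 / 40, A32 = 9.0 / 40;
static const double A41 = 44.0 / 45, A42 = -56.0 / 15, A43 = 32.0 / 9;
static const double A51 = 19372.0 / 6561, A52 = -25360.0 / 2187,
                    A53 = 64448.0 / 6561, A54 = -212.0 / 729;
static const double A61 = 9017.0 / 3168, A62 = -355.0 / 33,
                    A63 = 46732.0 / 5247, A64 = 49.0 / 176,
                    A65 = -5103.0 / 18656;
static const double B1 = 35.0 / 384, B3 = 500.0 / 1113, B4 = 125.0 / 192,
                    B5 = -2187.0 / 6784, B6 = 11.0 / 84;
static const double E1 = 35.0 / 384 - 5179.0 / 57600,
                    E3 = 500.0 / 1113 - 7571.0 / 16695,
                    E4 = 125.0 / 192 - 393.0 / 640,
                    E5 = -2187.0 / 6784 + 92097.0 / 339200,
                    E6 = 11.0 / 84 - 187.0 / 2100,
                    E7 = -1.0 / 40;

// Integrate from times_s[0] to times_s[end], writing the state at every
// requested time into out (nt x 4, row-major by R column order). Returns
// true on success; on failure *fail_t carries the failing time (seconds).
static bool integrate(const Model &m, const double *y0, const double *times_s,
                      int nt, double rtol, double atol_base, double *out,
                      int *n_clips, double *fail_t,
                      long maxsteps = 2000000) {
  double y[4], k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], k7[4], yt[4], ynew[4];
  double scale[4];
  for (int i = 0; i < 4; ++i) {
    y[i] = y0[i];
    scale[i] = atol_base * std::max(1.0, std::fabs(y0[i]));
  }
  *n_clips = 0;
  double t = times_s[0];
  for (int i = 0; i < 4; ++i) out[0 + nt * i] = y[i];

  rhs(m, y, k1);
  double h = 60.0;  // initial step: one minute
  long steps = 0;
  int iout = 1;
  if (nt == 1) return true;

  while (iout < nt) {
    const double tend = times_s[nt - 1];
    if (t + h > times_s[iout]) h = times_s[iout] - t;
    if (h < 1e-10 * std::max(1.0, std::fabs(t))) h = 1e-10 * std::max(1.0, std::fabs(t));
    if (++steps > maxsteps) { *fail_t = t; return false; }

    // FSAL: k1 already holds f(t, y)
    for (int i = 0; i < 4; ++i) yt[i] = y[i] + h * A21 * k1[i];
    rhs(m, yt, k2);
    for (int i = 0; i < 4; ++i) yt[i] = y[i] + h * (A31 * k1[i] + A32 * k2[i]);
    rhs(m, yt, k3);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + h * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
    rhs(m, yt, k4);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + h * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i] + A54 * k4[i]);
    rhs(m, yt, k5);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + h * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i] +
                          A64 * k4[i] + A65 * k5[i]);
    rhs(m, yt, k6);
    for (int i = 0; i < 4; ++i)
      ynew[i] = y[i] + h * (B1 * k1[i] + B3 * k3[i] + B4 * k4[i] +
                            B5 * k5[i] + B6 * k6[i]);
    rhs(m, ynew, k7);

    double errnorm = 0.0;
    for (int i = 0; i < 4; ++i) {
      const double err = h * (E1 * k1[i] + E3 * k3[i] + E4 * k4[i] +
                              E5 * k5[i] + E6 * k6[i] + E7 * k7[i]);
      const double sc = scale[i] + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      const double r = err / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / 4.0);
    if (!std::isfinite(errnorm)) { *fail_t = t; return false; }

    if (errnorm <= 1.0) {  // accept
      t += h;
      for (int i = 0; i < 4; ++i) {
        y[i] = ynew[i];
        if (y[i] < 0.0) { y[i] = 0.0; ++(*n_clips); }
        k1[i] = k7[i];
      }
      // a clip invalidates FSAL; recompute
      if (y[0] != ynew[0] || y[1] != ynew[1] || y[2] != ynew[2] || y[3] != ynew[3])
        rhs(m, y, k1);
      while (iout < nt && t >= times_s[iout] - 1e-9) {
        for (int i = 0; i < 4; ++i) out[iout + nt * i] = y[i];
        ++iout;
      }
      if (t >= tend - 1e-9 && iout >= nt) break;
    }
    double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h > 6.0 * 3600.0) h = 6.0 * 3600.0;  // cap: 6 h
    if (h < 1e-8) { *fail_t = t; return false; }
  }
  return true;
}

static Model make_model(const IntegerVector &kinds, const NumericVector &theta,
                        const NumericVector &consts) {
  Model m;
  m.k1 = kinds[0]; m.k2 = kinds[1]; m.k3 = kinds[2];
  m.beta = theta[0]; m.delta = theta[1]; m.Vg = theta[2];
  m.Ko = theta[3]; m.Kg = theta[4]; m.Kl = theta[5]; m.cbarg = theta[6];
  m.Vo = consts[0]; m.cbaro = consts[1]; m.nmax = consts[2];
  m.lsign = (consts.size() > 3) ? consts[3] : 1.0;
  return m;
}

// [[Rcpp::export]]
List ogl_solve_cpp(IntegerVector kinds, NumericVector theta,
                   NumericVector consts, NumericVector y0,
                   NumericVector times_h, double rtol, double atol) {
  const int nt = times_h.size();
  Model m = make_model(kinds, theta, consts);
  std::vector<double> ts(nt);
  for (int i = 0; i < nt; ++i) ts[i] = times_h[i] * 3600.0;
  NumericMatrix out(nt, 4);
  int n_clips = 0;
  double fail_t = NA_REAL;
  bool ok = integrate(m, &y0[0], ts.data(), nt, rtol, atol,
                      REAL(out), &n_clips, &fail_t);
  colnames(out) = CharacterVector::create("n", "cg", "cl", "co");
  return List::create(_["states"] = out, _["ok"] = ok,
                      _["n_clips"] = n_clips,
                      _["fail_time_h"] = ok ? NA_REAL : fail_t / 3600.0);
}

// Objective over packed conditions. Each element of conds is a list with
//   y0      numeric(4)
//   times_h numeric(nt), sorted, times_h[1] == 0 (initial condition row)
//   obs     nt x 3 matrix of means (n, cg, cl); NA = unobserved
//   w       nt x 3 matrix of weights (0 where unobserved)
static double objective_impl(const NumericVector &theta,
                             const IntegerVector &kinds,
                             const NumericVector &consts, const List &conds,
                             double rtol, double atol, double penalty) {
  double total = 0.0;
  Model m = make_model(kinds, theta, consts);
  for (int c = 0; c < conds.size(); ++c) {
    List cond = conds[c];
    NumericVector y0 = cond["y0"];
    NumericVector times_h = cond["times_h"];
    NumericMatrix obs = cond["obs"];
    NumericMatrix w = cond["w"];
    const int nt = times_h.size();
    std::vector<double> ts(nt), out(nt * 4);
    for (int i = 0; i < nt; ++i) ts[i] = times_h[i] * 3600.0;
    int n_clips = 0; double fail_t = 0.0;
    // tight step cap: pathological parameter proposals must fail fast,
    // not stall the multi-start search
    bool ok = integrate(m, &y0[0], ts.data(), nt, rtol, atol, out.data(),
                        &n_clips, &fail_t, 800);
    if (!ok) return penalty;
    for (int j = 0; j < 3; ++j) {       // observables n, cg, cl = state cols 0..2
      for (int i = 0; i < nt; ++i) {
        const double wij = w(i, j);
        if (wij > 0.0 && R_finite(obs(i, j))) {
          const double r = obs(i, j) - out[i + nt * j];
          total += 0.5 * wij * r * r;
        }
      }
    }
  }
  return total;
}

// [[Rcpp::export]]
double ogl_objective_cpp(NumericVector log10theta, IntegerVector kinds,
                         NumericVector consts, List conds, double rtol,
                         double atol, double penalty) {
  NumericVector theta(7);
  for (int i = 0; i < 7; ++i) theta[i] = std::pow(10.0, log10theta[i]);
  return objective_impl(theta, kinds, consts, conds, rtol, atol, penalty);
}

// Central finite-difference gradient in log10-parameter space.
// [[Rcpp::export]]
NumericVector ogl_objective_grad_cpp(NumericVector log10theta,
                                     IntegerVector kinds, NumericVector consts,
                                     List conds, double rtol, double atol,
                                     double penalty, double fd_step) {
  NumericVector g(7);
  NumericVector x = clone(log10theta);
  for (int i = 0; i < 7; ++i) {
    const double x0 = x[i];
    x[i] = x0 + fd_step;
    const double fp = ogl_objective_cpp(x, kinds, consts, conds, rtol, atol, penalty);
    x[i] = x0 - fd_step;
    const double fm = ogl_objective_cpp(x, kinds, consts, conds, rtol, atol, penalty);
    x[i] = x0;
    g[i] = (fp - fm) / (2.0 * fd_step);
  }
  return g;
}
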