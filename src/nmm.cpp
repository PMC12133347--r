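// Three-population ERP neural mass model: Euler integration of the 9-state
// delay-approximated ODE system, with forward sensitivity propagation for
// gradient-based inference. Parameter order throughout:
//   0 g1, 1 g2, 2 g3, 3 g4, 4 delta, 5 tau_e, 6 tau_i, 7 h_e, 8 h_i, 9 u
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NSTATE = 9;
static const int NPAR = 10;

static inline double sgm(double v) {
  return 1.0 / (1.0 + std::exp(-0.56 * v)) - 0.5;
}

static inline double dsgm(double v) {
  double s = 1.0 / (1.0 + std::exp(-0.56 * v));
  return 0.56 * s * (1.0 - s);
}

// Time derivatives of the nine states. Delayed arguments x(t - delta) inside
// the sigmoids are replaced by the first-order surrogate x - delta * xdot,
// which is closed-form because xdot of x1, x7, x9 are themselves states.
static inline void rhs(const double *x, const double *th, double uon, double *f) {
  const double g1 = th[0], g2 = th[1], g3 = th[2], g4 = th[3];
  const double del = th[4], te = th[5], ti = th[6];
  const double he = th[7], hi = th[8], u = th[9];
  const double d1 = x[0] - del * x[3];
  const double d7 = x[6] - del * x[7];
  const double d9 = x[8] - del * (x[4] - x[5]);
  const double s1 = sgm(d1), s7 = sgm(d7), s9 = sgm(d9);
  f[0] = x[3];
  f[1] = x[4];
  f[2] = x[5];
  f[3] = (he / te) * (g1 * s9 + u * uon) - x[0] / (te * te) - 2.0 * x[3] / te;
  f[4] = g2 * (he / te) * s1 - x[1] / (te * te) - 2.0 * x[4] / te;
  f[5] = g4 * (hi / ti) * s7 - x[2] / (ti * ti) - 2.0 * x[5] / ti;
  f[6] = x[7];
  f[7] = g3 * (he / te) * s9 - x[6] / (te * te) - 2.0 * x[7] / te;
  f[8] = x[4] - x[5];
}

static inline bool state_ok(const double *x, double bound) {
  for (int i = 0; i < NSTATE; ++i)
    if (!std::isfinite(x[i]) || std::fabs(x[i]) > bound) return false;
  return true;
}

// [[Rcpp::export(name = ".nmm_rhs_cpp")]]
NumericVector nmm_rhs_cpp(NumericVector x, NumericVector theta, double input_on) {
  NumericVector f(NSTATE);
  rhs(x.begin(), theta.begin(), input_on, f.begin());
  return f;
}

// Forward Euler from x0, recording every state. Aborts (and flags unstable)
// as soon as a state is non-finite or exceeds the blow-up bound; remaining
// rows are filled with NA so the trajectory is self-describing.
// [[Rcpp::export(name = ".nmm_integrate_cpp")]]
List nmm_integrate_cpp(NumericVector theta, NumericVector x0, double dt,
                       int n_steps, double input_on, double blowup) {
  NumericMatrix states(n_steps + 1, NSTATE);
  double x[NSTATE], f[NSTATE];
  for (int i = 0; i < NSTATE; ++i) x[i] = x0[i];
  bool stable = state_ok(x, blowup);
  int n_valid = 0;
  for (int k = 0; k <= n_steps; ++k) {
    if (!stable) {
      for (int i = 0; i < NSTATE; ++i) states(k, i) = NA_REAL;
      continue;
    }
    for (int i = 0; i < NSTATE; ++i) states(k, i) = x[i];
    n_valid = k + 1;
    if (k < n_steps) {
      rhs(x, theta.begin(), input_on, f);
      for (int i = 0; i < NSTATE; ++i) x[i] += dt * f[i];
      if (!state_ok(x, blowup)) stable = false;
    }
  }
  return List::create(_["states"] = states, _["stable"] = stable,
                      _["n_valid"] = n_valid);
}

// Pyramidal voltage x9 at every ds-th step (starting at step 0), without
// storing the full trajectory.
// [[Rcpp::export(name = ".nmm_predict_cpp")]]
List nmm_predict_cpp(NumericVector theta, double dt, int n_steps, int ds,
                     double input_on, double blowup) {
  int n_out = n_steps / ds + 1;
  NumericVector pred(n_out, NA_REAL);
  double x[NSTATE] = {0}, f[NSTATE];
  bool stable = true;
  int j = 0;
  for (int k = 0; k <= n_steps; ++k) {
    if (k % ds == 0) pred[j++] = x[8];
    if (k < n_steps) {
      rhs(x, theta.begin(), input_on, f);
      for (int i = 0; i < NSTATE; ++i) x[i] += dt * f[i];
      if (!state_ok(x, blowup)) { stable = false; break; }
    }
  }
  return List::create(_["pred"] = pred, _["stable"] = stable);
}

// Gaussian log-likelihood of the downsampled pyramidal voltage and its
// gradient with respect to all ten parameters, by forward sensitivity
// analysis: S = dx/dtheta obeys S' = J_x S + J_theta along the Euler path.
// J_x is sparse (<= 5 entries per row), exploited below. Returns the
// pointwise log-likelihood vector (needed by WAIC / PSIS-LOO), the clean
// prediction, total log-likelihood, gradient, and a stability flag; an
// unstable draw yields -Inf log-likelihood and a zero gradient.
// [[Rcpp::export(name = ".nmm_loglik_grad_cpp")]]
List nmm_loglik_grad_cpp(NumericVector theta, NumericVector y, double dt,
                         int n_steps, int ds, double sigma, double input_on,
                         double blowup, bool want_grad) {
  const int n_out = n_steps / ds + 1;
  const double g1 = theta[0], g2 = theta[1], g3 = theta[2], g4 = theta[3];
  const double del = theta[4], te = theta[5], ti = theta[6];
  const double he = theta[7], hi = theta[8], u = theta[9];
  const double te2 = te * te, ti2 = ti * ti;

  NumericVector pred(n_out, NA_REAL), pw(n_out, NA_REAL), grad(NPAR);
  NumericMatrix pred_sens(want_grad ? n_out : 1, NPAR);

  double x[NSTATE] = {0}, f[NSTATE];
  // S[i][p] = d x_i / d theta_p ; zero initial condition (x0 independent of theta)
  double S[NSTATE][NPAR] = {{0}}, dS[NSTATE][NPAR];
  bool stable = true;
  int j = 0;

  for (int k = 0; k <= n_steps; ++k) {
    if (k % ds == 0) {
      pred[j] = x[8];
      if (want_grad)
        for (int p = 0; p < NPAR; ++p) pred_sens(j, p) = S[8][p];
      ++j;
    }
    if (k == n_steps) break;

    const double d1 = x[0] - del * x[3];
    const double d7 = x[6] - del * x[7];
    const double d9 = x[8] - del * (x[4] - x[5]);
    // logistic values shared between the sigmoid and its derivative
    const double l1 = 1.0 / (1.0 + std::exp(-0.56 * d1));
    const double l7 = 1.0 / (1.0 + std::exp(-0.56 * d7));
    const double l9 = 1.0 / (1.0 + std::exp(-0.56 * d9));
    const double s1 = l1 - 0.5, s7 = l7 - 0.5, s9 = l9 - 0.5;

    f[0] = x[3];
    f[1] = x[4];
    f[2] = x[5];
    f[3] = (he / te) * (g1 * s9 + u * input_on) - x[0] / te2 - 2.0 * x[3] / te;
    f[4] = g2 * (he / te) * s1 - x[1] / te2 - 2.0 * x[4] / te;
    f[5] = g4 * (hi / ti) * s7 - x[2] / ti2 - 2.0 * x[5] / ti;
    f[6] = x[7];
    f[7] = g3 * (he / te) * s9 - x[6] / te2 - 2.0 * x[7] / te;
    f[8] = x[4] - x[5];

    if (want_grad) {
      const double ds1 = 0.56 * l1 * (1.0 - l1);
      const double ds7 = 0.56 * l7 * (1.0 - l7);
      const double ds9 = 0.56 * l9 * (1.0 - l9);
      const double a4 = (he / te) * g1 * ds9;
      const double a5 = g2 * (he / te) * ds1;
      const double a6 = g4 * (hi / ti) * ds7;
      const double a8 = g3 * (he / te) * ds9;
      for (int p = 0; p < NPAR; ++p) {
        const double Sd1 = S[0][p] - del * S[3][p];
        const double Sd7 = S[6][p] - del * S[7][p];
        const double Sd9 = S[8][p] - del * (S[4][p] - S[5][p]);
        dS[0][p] = S[3][p];
        dS[1][p] = S[4][p];
        dS[2][p] = S[5][p];
        dS[3][p] = a4 * Sd9 - S[0][p] / te2 - 2.0 * S[3][p] / te;
        dS[4][p] = a5 * Sd1 - S[1][p] / te2 - 2.0 * S[4][p] / te;
        dS[5][p] = a6 * Sd7 - S[2][p] / ti2 - 2.0 * S[5][p] / ti;
        dS[6][p] = S[7][p];
        dS[7][p] = a8 * Sd9 - S[6][p] / te2 - 2.0 * S[7][p] / te;
        dS[8][p] = S[4][p] - S[5][p];
      }
      // explicit J_theta contributions (rows f4, f5, f6, f8 only)
      dS[3][0] += (he / te) * s9;                                   // g1
      dS[3][4] += -a4 * (x[4] - x[5]);                              // delta
      dS[3][5] += -(he / te2) * (g1 * s9 + u * input_on)
                  + 2.0 * x[0] / (te2 * te) + 2.0 * x[3] / te2;     // tau_e
      dS[3][7] += (g1 * s9 + u * input_on) / te;                    // h_e
      dS[3][9] += (he / te) * input_on;                             // u

      dS[4][1] += (he / te) * s1;                                   // g2
      dS[4][4] += -a5 * x[3];                                       // delta
      dS[4][5] += -g2 * he * s1 / te2
                  + 2.0 * x[1] / (te2 * te) + 2.0 * x[4] / te2;     // tau_e
      dS[4][7] += g2 * s1 / te;                                     // h_e

      dS[5][3] += (hi / ti) * s7;                                   // g4
      dS[5][4] += -a6 * x[7];                                       // delta
      dS[5][6] += -g4 * hi * s7 / ti2
                  + 2.0 * x[2] / (ti2 * ti) + 2.0 * x[5] / ti2;     // tau_i
      dS[5][8] += g4 * s7 / ti;                                     // h_i

      dS[7][2] += (he / te) * s9;                                   // g3
      dS[7][4] += -a8 * (x[4] - x[5]);                              // delta
      dS[7][5] += -g3 * he * s9 / te2
                  + 2.0 * x[6] / (te2 * te) + 2.0 * x[7] / te2;     // tau_e
      dS[7][7] += g3 * s9 / te;                                     // h_e

      for (int i = 0; i < NSTATE; ++i)
        for (int p = 0; p < NPAR; ++p) S[i][p] += dt * dS[i][p];
    }
    for (int i = 0; i < NSTATE; ++i) x[i] += dt * f[i];
    if (!state_ok(x, blowup)) { stable = false; break; }
    if (want_grad) {
      for (int i = 0; i < NSTATE && stable; ++i)
        for (int p = 0; p < NPAR; ++p)
          if (!std::isfinite(S[i][p])) { stable = false; break; }
      if (!stable) break;
    }
  }

  double ll = 0.0;
  if (stable) {
    const double lc = -0.5 * std::log(2.0 * M_PI) - std::log(sigma);
    const double inv_s2 = 1.0 / (sigma * sigma);
    for (int i = 0; i < n_out; ++i) {
      const double r = y[i] - pred[i];
      pw[i] = lc - 0.5 * r * r * inv_s2;
      ll += pw[i];
      if (want_grad)
        for (int p = 0; p < NPAR; ++p) grad[p] += r * inv_s2 * pred_sens(i, p);
    }
  } else {
    ll = R_NegInf;
    std::fill(pw.begin(), pw.end(), R_NegInf);
    std::fill(grad.begin(), grad.end(), 0.0);
  }
  return List::create(_["loglik"] = ll, _["grad"] = grad, _["pointwise"] = pw,
                      _["pred"] = pred, _["stable"] = stable);
}
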