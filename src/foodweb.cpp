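#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Reduced plankton food web, single carbon currency with fixed P:C quota.
// State (7): P1 P2 Z1 Z2 B D N  -- carbon pools in mgC m^-3, N in mmolP m^-3.
// Parameter vector layout (see foodweb_par_vector() on the R side):
//  0  q        P:C quota (mmolP per mgC)
//  1  f_I      light limitation factor [0,1]
//  2  T_ref    reference temperature (degC)
//  3  Q10_p    Q10, all organisms except bacteria
//  4  Q10_b    Q10, heterotrophic bacteria
//  5..6   r1 r2        producer max growth rates (1/d)
//  7..8   kN1 kN2      nutrient half-saturation (mmolP m^-3)
//  9..10  sp1 sp2      producer basal respiration (1/d)
//  11..12 xp1 xp2      producer excretion (1/d)
//  13..14 mp1 mp2      producer mortality (1/d)
//  15..19 g1 K1 w1P1 w1P2 w1B      microzooplankton grazing
//  20..24 g2 K2 w2P1 w2P2 w2Z1     mesozooplankton grazing
//  25..26 eta beta     assimilation efficiency, excreted fraction of uptake
//  27..28 sz1 sz2      zooplankton respiration (1/d)
//  29..30 mz1 mz2      zooplankton mortality (1/d)
//  31..34 uB kD eB sB  bacteria: max uptake, half-sat (mgC), growth eff., respiration

static inline void deriv(const double *x, double T, const double *p,
                         double *dx) {
  const double q = p[0], fI = p[1], Tref = p[2];
  const double fTp = std::pow(p[3], (T - Tref) / 10.0);
  const double fTb = std::pow(p[4], (T - Tref) / 10.0);
  const double P1 = x[0], P2 = x[1], Z1 = x[2], Z2 = x[3], B = x[4],
               D = x[5], N = x[6];

  // producers
  const double gpp1 = p[5] * fTp * fI * (N / (N + p[7])) * P1;
  const double gpp2 = p[6] * fTp * fI * (N / (N + p[8])) * P2;
  const double rsp1 = p[9] * fTp * P1, rsp2 = p[10] * fTp * P2;
  const double exc1 = p[11] * fTp * P1, exc2 = p[12] * fTp * P2;
  const double mor1 = p[13] * P1, mor2 = p[14] * P2;

  // microzooplankton Z1 grazes P1, P2, B: Holling type II on the effective
  // food with abundance-based prey switching (effort tracks the square of
  // weighted prey density), which gives rare prey a grazing refuge
  const double a11 = p[17] * P1, a12 = p[18] * P2, a13 = p[19] * B;
  const double s1 = a11 + a12 + a13;
  const double s1q = a11 * P1 + a12 * P2 + a13 * B;
  const double F1 = (s1 > 0.0) ? s1q / s1 : 0.0;
  const double G1 = p[15] * fTp * (F1 / (p[16] + F1)) * Z1;
  const double G1P1 = (s1q > 0.0) ? G1 * a11 * P1 / s1q : 0.0;
  const double G1P2 = (s1q > 0.0) ? G1 * a12 * P2 / s1q : 0.0;
  const double G1B  = (s1q > 0.0) ? G1 * a13 * B  / s1q : 0.0;

  // mesozooplankton Z2 grazes P1, P2, Z1 the same way
  const double a21 = p[22] * P1, a22 = p[23] * P2, a23 = p[24] * Z1;
  const double s2 = a21 + a22 + a23;
  const double s2q = a21 * P1 + a22 * P2 + a23 * Z1;
  const double F2 = (s2 > 0.0) ? s2q / s2 : 0.0;
  const double G2 = p[20] * fTp * (F2 / (p[21] + F2)) * Z2;
  const double G2P1 = (s2q > 0.0) ? G2 * a21 * P1 / s2q : 0.0;
  const double G2P2 = (s2q > 0.0) ? G2 * a22 * P2 / s2q : 0.0;
  const double G2Z1 = (s2q > 0.0) ? G2 * a23 * Z1 / s2q : 0.0;

  const double eta = p[25], beta = p[26];
  const double rz1 = p[27] * fTp * Z1, rz2 = p[28] * fTp * Z2;
  const double mz1 = p[29] * Z1, mz2 = p[30] * Z2;

  // bacteria remineralize detritus/DOM back to the nutrient pool
  const double upt = p[31] * fTb * (D / (D + p[32])) * B;
  const double eB = p[33];
  const double rB = p[34] * fTb * B;

  dx[0] = gpp1 - rsp1 - exc1 - mor1 - G1P1 - G2P1;
  dx[1] = gpp2 - rsp2 - exc2 - mor2 - G1P2 - G2P2;
  dx[2] = eta * (1.0 - beta) * G1 - rz1 - mz1 - G2Z1;
  dx[3] = eta * (1.0 - beta) * G2 - rz2 - mz2;
  dx[4] = eB * upt - rB - G1B;
  dx[5] = exc1 + exc2 + mor1 + mor2 + (1.0 - eta) * (G1 + G2) + mz1 + mz2 - upt;
  // nutrient balance closes the phosphorus cycle exactly
  dx[6] = q * (-(gpp1 + gpp2) + rsp1 + rsp2 + eta * beta * (G1 + G2) +
               rz1 + rz2 + (1.0 - eB) * upt + rB);
}

// one classical RK4 step; temperature linearly interpolated inside the step
static inline void rk4_step(double *x, double T0, double T1, double dt,
                            const double *p, double *work) {
  double *k1 = work, *k2 = work + 7, *k3 = work + 14, *k4 = work + 21,
         *xt = work + 28;
  const double Tm = 0.5 * (T0 + T1);
  deriv(x, T0, p, k1);
  for (int i = 0; i < 7; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
  deriv(xt, Tm, p, k2);
  for (int i = 0; i < 7; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
  deriv(xt, Tm, p, k3);
  for (int i = 0; i < 7; ++i) xt[i] = x[i] + dt * k3[i];
  deriv(xt, T1, p, k4);
  for (int i = 0; i < 7; ++i)
    x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// clip tiny integrator undershoots; anything larger is a genuine failure
static inline bool clip_state(double *x, double tol) {
  for (int i = 0; i < 7; ++i) {
    if (x[i] < 0.0) {
      if (x[i] < -tol) return false;
      x[i] = 0.0;
    }
    if (!std::isfinite(x[i])) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".foodweb_derivatives_cpp")]]
NumericVector foodweb_derivatives_cpp(NumericVector state, double T,
                                      NumericVector par) {
  NumericVector out(7);
  deriv(REAL(state), T, REAL(par), REAL(out));
  return out;
}

// [[Rcpp::export(name = ".foodweb_integrate_cpp")]]
List foodweb_integrate_cpp(NumericVector state0, NumericVector par,
                           NumericVector temperature, double dt,
                           double clip_tol = 1e-8) {
  const int n_steps = temperature.size() - 1;
  if (n_steps < 1) stop("temperature grid must have at least 2 samples");
  NumericMatrix out(n_steps + 1, 7);
  double x[7], work[35];
  for (int i = 0; i < 7; ++i) { x[i] = state0[i]; out(0, i) = x[i]; }
  const double *p = REAL(par);
  const double *Tv = REAL(temperature);
  for (int k = 0; k < n_steps; ++k) {
    rk4_step(x, Tv[k], Tv[k + 1], dt, p, work);
    if (!clip_state(x, clip_tol))
      return List::create(_["status"] = 1, _["fail_step"] = k + 1,
                          _["state"] = out);
    for (int i = 0; i < 7; ++i) out(k + 1, i) = x[i];
  }
  return List::create(_["status"] = 0, _["state"] = out);
}

// Wolf-style maximal Lyapunov exponent through the known dynamics:
// a companion trajectory at small separation is advanced with the main one
// and renormalized at fixed intervals; lambda is the mean log stretching
// rate per unit time. Temperature grid covers transient + measurement.
// [[Rcpp::export(name = ".foodweb_lyapunov_cpp")]]
List foodweb_lyapunov_cpp(NumericVector state0, NumericVector par,
                          NumericVector temperature, double dt,
                          int transient_steps, double d0 = 1e-7,
                          int renorm_every = 14, double clip_tol = 1e-8) {
  const int n_steps = temperature.size() - 1;
  if (transient_steps >= n_steps) stop("transient longer than run");
  double x[7], y[7], work[35];
  for (int i = 0; i < 7; ++i) x[i] = state0[i];
  const double *p = REAL(par);
  const double *Tv = REAL(temperature);
  for (int k = 0; k < transient_steps; ++k) {
    rk4_step(x, Tv[k], Tv[k + 1], dt, p, work);
    if (!clip_state(x, clip_tol))
      return List::create(_["status"] = 1, _["lambda"] = NA_REAL);
  }
  // seed the companion at separation d0 relative to the state norm, with
  // the perturbation projected onto the constant-mass subspace: the total
  // phosphorus q*(sum of carbon pools) + N is a linear invariant of the
  // flow, so a mass-carrying component would add a spurious neutral
  // direction to the divergence measurement
  double scale = 0.0;
  for (int i = 0; i < 7; ++i) scale += x[i] * x[i];
  scale = std::sqrt(scale);
  if (scale <= 0.0)
    return List::create(_["status"] = 2, _["lambda"] = NA_REAL);
  const double dsep = d0 * scale;
  double g[7], u[7];
  {
    const double q = p[0];
    double gn = 0.0;
    for (int i = 0; i < 6; ++i) { g[i] = q; gn += q * q; }
    g[6] = 1.0; gn += 1.0;
    gn = std::sqrt(gn);
    for (int i = 0; i < 7; ++i) g[i] /= gn;
    double dot = 0.0;
    for (int i = 0; i < 7; ++i) { u[i] = 1.0; dot += g[i]; }
    double un = 0.0;
    for (int i = 0; i < 7; ++i) { u[i] -= dot * g[i]; un += u[i] * u[i]; }
    un = std::sqrt(un);
    for (int i = 0; i < 7; ++i) y[i] = x[i] + dsep * u[i] / un;
  }
  double sum_log = 0.0;
  int n_renorm = 0;
  double worky[35];
  for (int k = transient_steps; k < n_steps; ++k) {
    rk4_step(x, Tv[k], Tv[k + 1], dt, p, work);
    rk4_step(y, Tv[k], Tv[k + 1], dt, p, worky);
    if (!clip_state(x, clip_tol))
      return List::create(_["status"] = 1, _["lambda"] = NA_REAL);
    if ((k - transient_steps + 1) % renorm_every == 0) {
      double d1 = 0.0;
      for (int i = 0; i < 7; ++i) d1 += (y[i] - x[i]) * (y[i] - x[i]);
      d1 = std::sqrt(d1);
      if (d1 <= 0.0) d1 = 1e-300;  // exactly coincident orbits
      sum_log += std::log(d1 / dsep);
      // rescale and re-project onto the constant-mass subspace (the flow
      // preserves it exactly; this only removes roundoff drift)
      double w[7], dot = 0.0;
      for (int i = 0; i < 7; ++i) { w[i] = y[i] - x[i]; dot += w[i] * g[i]; }
      double wn = 0.0;
      for (int i = 0; i < 7; ++i) { w[i] -= dot * g[i]; wn += w[i] * w[i]; }
      wn = std::sqrt(wn);
      if (wn <= 0.0) wn = 1e-300;
      for (int i = 0; i < 7; ++i) y[i] = x[i] + w[i] * (dsep / wn);
      ++n_renorm;
    }
  }
  const double time_span = n_renorm * renorm_every * dt;
  return List::create(_["status"] = 0,
                      _["lambda"] = time_span > 0 ? sum_log / time_span : NA_REAL,
                      _["n_renorm"] = n_renorm);
}
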