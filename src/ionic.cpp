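#include <Rcpp.h>
#include "lr1.h"
using namespace Rcpp;

// Exact-rate 0-D interface to the Luo-Rudy I kinetics. State vectors are
// ordered (m, h, j, d, f, X, Cai).

// [[Rcpp::export]]
NumericVector lr1_rates_cpp(double v) {
  lr1::Rates r = lr1::rates(v);
  NumericVector out = NumericVector::create(
      _["alpha_m"] = r.am, _["beta_m"] = r.bm,
      _["alpha_h"] = r.ah, _["beta_h"] = r.bh,
      _["alpha_j"] = r.aj, _["beta_j"] = r.bj,
      _["alpha_d"] = r.ad, _["beta_d"] = r.bd,
      _["alpha_f"] = r.af, _["beta_f"] = r.bf,
      _["alpha_X"] = r.ax, _["beta_X"] = r.bx);
  return out;
}

// [[Rcpp::export]]
NumericVector lr1_currents_cpp(double v, NumericVector state) {
  double c[6];
  lr1::currents(v, REAL(state), c);
  return NumericVector::create(
      _["I_Na"] = c[0], _["I_si"] = c[1], _["I_K"] = c[2],
      _["I_K1"] = c[3], _["I_Kp"] = c[4], _["I_b"] = c[5]);
}

// rush_larsen: exponential integrator w -> winf + (w - winf)*exp(-dt/tau)
// [[Rcpp::export]]
NumericVector lr1_step_gates_cpp(double v, NumericVector state, double dt,
                                 int n_steps, bool rush_larsen) {
  NumericVector s = clone(state);
  double* p = REAL(s);
  lr1::Rates r = lr1::rates(v);
  double a[6] = { r.am, r.ah, r.aj, r.ad, r.af, r.ax };
  double b[6] = { r.bm, r.bh, r.bj, r.bd, r.bf, r.bx };
  double decay[6], winf[6];
  if (rush_larsen) {
    for (int g = 0; g < 6; ++g) {
      double rate = a[g] + b[g];
      winf[g] = (rate > 0) ? a[g] / rate : 0.0;
      decay[g] = std::exp(-dt * rate);
    }
  }
  for (int i = 0; i < n_steps; ++i) {
    double dCai = -1e-4 * lr1::Gsi * p[3] * p[4] *
                      (v - (7.7 - 13.0287 * std::log(p[6]))) +
                  0.07 * (1e-4 - p[6]);
    if (rush_larsen) {
      for (int g = 0; g < 6; ++g)
        p[g] = winf[g] + (p[g] - winf[g]) * decay[g];
    } else {
      lr1::step_gates_exact(v, p, dt);
    }
    p[6] += dt * dCai;
    if (p[6] < 1e-8) p[6] = 1e-8;
  }
  return s;
}

// Unstimulated/stimulated 0-D forward-Euler run with exact rates.
// stim_amp in uA/cm^2 (membrane current density), depolarizing when > 0.
// [[Rcpp::export]]
List lr1_run0d_cpp(double v0, NumericVector state, double dt, double t_end,
                   double stim_amp, double stim_start, double stim_dur,
                   double record_dt) {
  double Cm = 1.0;  // uF/cm^2, membrane-referenced 0-D cell
  NumericVector s = clone(state);
  double* p = REAL(s);
  double v = v0;
  long n_steps = (long)std::ceil(t_end / dt);
  int stride = std::max(1, (int)std::lround(record_dt / dt));
  long n_rec = n_steps / stride + 1;
  NumericVector tout(n_rec), vout(n_rec);
  double max_dvdt = -1e300;
  long r = 0;
  tout[0] = 0.0; vout[0] = v;
  r = 1;
  for (long it = 0; it < n_steps; ++it) {
    double t = it * dt;
    double dCai;
    double Iion = lr1::total_current(v, p, &dCai);
    double Istim = (t >= stim_start && t < stim_start + stim_dur) ? stim_amp : 0.0;
    double dvdt = (-Iion + Istim) / Cm;
    if (dvdt > max_dvdt) max_dvdt = dvdt;
    lr1::step_gates_exact(v, p, dt);
    p[6] += dt * dCai;
    if (p[6] < 1e-8) p[6] = 1e-8;
    v += dt * dvdt;
    if (!std::isfinite(v))
      stop("0-D integration diverged at t = %f ms", t);
    if (((it + 1) % stride == 0) && r < n_rec) {
      tout[r] = (it + 1) * dt;
      vout[r] = v;
      ++r;
    }
  }
  return List::create(_["time"] = tout[Range(0, r - 1)],
                      _["v"] = vout[Range(0, r - 1)],
                      _["v_final"] = v, _["state"] = s,
                      _["max_dvdt"] = max_dvdt);
}
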