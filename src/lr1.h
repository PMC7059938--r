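#ifndef GJCABLE_LR1_H
#define GJCABLE_LR1_H

#include <cmath>
#include <vector>

// Luo-Rudy phase-I (1991) ventricular kinetics, [K]o = 5.4 mM parameter set.
// Units: mV, ms, uA/cm^2, mM. State order: m, h, j, d, f, X, Cai.

namespace lr1 {

const double GNa = 23.0;      // mS/cm^2
const double ENa = 54.4;      // mV
const double Gsi = 0.09;
const double GK  = 0.282;     // 0.282*sqrt(Ko/5.4), Ko = 5.4
const double EK  = -77.0;
const double GK1 = 0.6047;    // 0.6047*sqrt(Ko/5.4)
const double RTF = 8314.472 * 310.0 / 96485.3415;   // mV
inline double EK1() {
  static const double val = RTF * std::log(5.4 / 145.0);
  return val;
}
const double GKp = 0.0183;
const double Gb  = 0.03921;
const double Eb  = -59.87;

struct Rates {
  double am, bm, ah, bh, aj, bj, ad, bd, af, bf, ax, bx;
};

inline Rates rates(double v) {
  Rates r;
  double dvm = v + 47.13;
  r.am = (std::fabs(dvm) < 1e-7) ? 3.2
       : 0.32 * dvm / (1.0 - std::exp(-0.1 * dvm));
  r.bm = 0.08 * std::exp(-v / 11.0);
  if (v < -40.0) {
    r.ah = 0.135 * std::exp((80.0 + v) / -6.8);
    r.bh = 3.56 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.35 * v);
    r.aj = (-1.2714e5 * std::exp(0.2444 * v) - 3.474e-5 * std::exp(-0.04391 * v)) *
           (v + 37.78) / (1.0 + std::exp(0.311 * (v + 79.23)));
    r.bj = 0.1212 * std::exp(-0.01052 * v) / (1.0 + std::exp(-0.1378 * (v + 40.14)));
  } else {
    r.ah = 0.0;
    r.bh = 1.0 / (0.13 * (1.0 + std::exp((v + 10.66) / -11.1)));
    r.aj = 0.0;
    r.bj = 0.3 * std::exp(-2.535e-7 * v) / (1.0 + std::exp(-0.1 * (v + 32.0)));
  }
  r.ad = 0.095 * std::exp(-0.01 * (v - 5.0)) / (1.0 + std::exp(-0.072 * (v - 5.0)));
  r.bd = 0.07  * std::exp(-0.017 * (v + 44.0)) / (1.0 + std::exp(0.05 * (v + 44.0)));
  r.af = 0.012 * std::exp(-0.008 * (v + 28.0)) / (1.0 + std::exp(0.15 * (v + 28.0)));
  r.bf = 0.0065 * std::exp(-0.02 * (v + 30.0)) / (1.0 + std::exp(-0.2 * (v + 30.0)));
  r.ax = 0.0005 * std::exp(0.083 * (v + 50.0)) / (1.0 + std::exp(0.057 * (v + 50.0)));
  r.bx = 0.0013 * std::exp(-0.06 * (v + 20.0)) / (1.0 + std::exp(-0.04 * (v + 20.0)));
  return r;
}

// time-independent K current shape factor
inline double Xi(double v) {
  if (v <= -100.0) return 1.0;
  if (std::fabs(v + 77.0) < 1e-6)
    return 2.837 * 0.04 / std::exp(0.04 * (v + 35.0));
  return 2.837 * (std::exp(0.04 * (v + 77.0)) - 1.0) /
         ((v + 77.0) * std::exp(0.04 * (v + 35.0)));
}

inline double K1inf(double v) {
  double ek1 = EK1();
  double a = 1.02 / (1.0 + std::exp(0.2385 * (v - ek1 - 59.215)));
  double b = (0.49124 * std::exp(0.08032 * (v - ek1 + 5.476)) +
              std::exp(0.06175 * (v - ek1 - 594.31))) /
             (1.0 + std::exp(-0.5143 * (v - ek1 + 4.753)));
  return a / (a + b);
}

inline double Kp(double v) {
  return 1.0 / (1.0 + std::exp((7.488 - v) / 5.98));
}

// six currents, uA/cm^2; out[0..5] = INa, Isi, IK, IK1, IKp, Ib
inline void currents(double v, const double* s, double* out) {
  double m = s[0], h = s[1], j = s[2], d = s[3], f = s[4], X = s[5], Cai = s[6];
  double Esi = 7.7 - 13.0287 * std::log(Cai);
  out[0] = GNa * m * m * m * h * j * (v - ENa);
  out[1] = Gsi * d * f * (v - Esi);
  out[2] = GK * X * Xi(v) * (v - EK);
  out[3] = GK1 * K1inf(v) * (v - EK1());
  out[4] = GKp * Kp(v) * (v - EK1());
  out[5] = Gb * (v - Eb);
}

inline double total_current(double v, const double* s, double* dCai) {
  double c[6];
  currents(v, s, c);
  if (dCai) *dCai = -1e-4 * c[1] + 0.07 * (1e-4 - s[6]);
  return c[0] + c[1] + c[2] + c[3] + c[4] + c[5];
}

// exact forward-Euler gate update (rates evaluated exactly)
inline void step_gates_exact(double v, double* s, double dt) {
  Rates r = rates(v);
  double a[6] = { r.am, r.ah, r.aj, r.ad, r.af, r.ax };
  double b[6] = { r.bm, r.bh, r.bj, r.bd, r.bf, r.bx };
  for (int g = 0; g < 6; ++g) {
    s[g] += dt * (a[g] - (a[g] + b[g]) * s[g]);
    if (s[g] < 1e-12) s[g] = 0.0;  // also flushes subnormal closed gates
    if (s[g] > 1.0) s[g] = 1.0;
  }
}

// Rate lookup tables on a uniform voltage grid, used only inside the strand
// solvers (the 0-D interface evaluates rates exactly). Linear interpolation.
// One interleaved row per grid voltage so a node update touches two
// contiguous rows: [alpha_g (6), alpha_g+beta_g (6), GK*Xi, GK1*K1inf,
// GKp*Kp, pad] = 16 doubles.
struct RateTab {
  static const int W = 16;
  double vmin, dv, inv_dv, ek1;
  int n;
  std::vector<double> row;

  RateTab(double vlo = -150.0, double vhi = 100.0, double step = 0.05)
      : vmin(vlo), dv(step), inv_dv(1.0 / step), ek1(EK1()) {
    n = (int)std::floor((vhi - vlo) / step) + 1;
    row.assign((size_t)n * W, 0.0);
    for (int k = 0; k < n; ++k) {
      double v = vmin + k * dv;
      Rates r = rates(v);
      double a[6] = { r.am, r.ah, r.aj, r.ad, r.af, r.ax };
      double b[6] = { r.bm, r.bh, r.bj, r.bd, r.bf, r.bx };
      double* p = &row[(size_t)k * W];
      for (int g = 0; g < 6; ++g) { p[g] = a[g]; p[6 + g] = a[g] + b[g]; }
      p[12] = GK * Xi(v);
      p[13] = GK1 * K1inf(v);
      p[14] = GKp * Kp(v);
    }
  }
};

// One forward-Euler membrane update at a node via the rate tables:
// returns Iion(v, s) evaluated at the incoming state, then advances the
// gates and Cai in place. Esi (the slow-inward reversal potential, a slow
// function of Cai) is supplied by the caller, which refreshes it
// periodically rather than evaluating the logarithm every step.
inline double node_membrane(const RateTab& tab, double v, double* s, double dt,
                            double Esi) {
  double u = (v - tab.vmin) * tab.inv_dv;
  int k;
  double w;
  if (u <= 0.0) { k = 0; w = 0.0; }
  else if (u >= tab.n - 1) { k = tab.n - 2; w = 1.0; }
  else { k = (int)u; w = u - k; }
  const double* p0 = &tab.row[(size_t)k * RateTab::W];
  const double* p1 = p0 + RateTab::W;

  double m = s[0], h = s[1], j = s[2], d = s[3], f = s[4], X = s[5], Cai = s[6];
  double Isi = Gsi * d * f * (v - Esi);
  double ek1 = tab.ek1;
  double Iion = GNa * m * m * m * h * j * (v - ENa) + Isi +
                (p0[12] + w * (p1[12] - p0[12])) * X * (v - EK) +
                (p0[13] + w * (p1[13] - p0[13])) * (v - ek1) +
                (p0[14] + w * (p1[14] - p0[14])) * (v - ek1) +
                Gb * (v - Eb);

  for (int g = 0; g < 6; ++g) {
    double a = p0[g] + w * (p1[g] - p0[g]);
    double b = p0[6 + g] + w * (p1[6 + g] - p0[6 + g]);
    double sg = s[g] + dt * (a - b * s[g]);
    if (sg < 1e-12) sg = 0.0;  // also flushes subnormal closed gates
    if (sg > 1.0) sg = 1.0;
    s[g] = sg;
  }
  s[6] = Cai + dt * (-1e-4 * Isi + 0.07 * (1e-4 - Cai));
  if (s[6] < 1e-8) s[6] = 1e-8;
  return Iion;
}

inline double esi_of(double Cai) { return 7.7 - 13.0287 * std::log(Cai); }

} // namespace lr1

#endif
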