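#include <Rcpp.h>
#include "lr1.h"
#if defined(__SSE2__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
using namespace Rcpp;

// Subnormal gate/current magnitudes (~1e-308) are physically meaningless
// here but cost two orders of magnitude per arithmetic op; flush them to
// zero inside the solvers and restore the FP environment on exit.
struct FtzGuard {
#if defined(__SSE2__)
  unsigned int saved;
  FtzGuard() : saved(_mm_getcsr()) {
    _mm_setcsr(saved | 0x8040);  // FTZ | DAZ
  }
  ~FtzGuard() { _mm_setcsr(saved); }
#endif
};

// Normalized gap-junction conductance g_j(Vj).
// regime: 0 = clamped (g == 1), 1 = instantaneous, 2 = steady-state.
// Parameter packing (12 doubles):
//   [0..3]  G_neg, G_pos, VH_neg, VH_pos            (instantaneous)
//   [4..11] gmin_neg, gmin_pos, A_neg, A_pos,
//           Vj0_neg, Vj0_pos, p, d                  (steady-state)
// Branch ties (Vj = 0, Vj = d) take the negative-polarity branch.
static inline double gj_eval(int regime, double vj, const double* p) {
  if (regime == 0) return 1.0;
  if (regime == 1) {
    double G, VH;
    if (vj <= 0.0) { G = p[0]; VH = p[2]; } else { G = p[1]; VH = p[3]; }
    return G * (2.0 * std::cosh(vj / VH) - 1.0) / (0.5 * (p[0] + p[1]));
  }
  double gmin, A, V0;
  if (vj <= p[11]) { gmin = p[4]; A = p[6]; V0 = p[8]; }
  else             { gmin = p[5]; A = p[7]; V0 = p[9]; }
  double ex = std::exp(A * (vj - V0));
  return (1.0 - gmin) / (p[10] + ex) + gmin;
}

// [[Rcpp::export]]
NumericVector gj_eval_cpp(NumericVector vj, int regime, NumericVector gjp) {
  int n = vj.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = gj_eval(regime, vj[i], REAL(gjp));
  return out;
}

struct Recorder {
  int stride, n_rec, n_nodes;
  long count;
  NumericMatrix v;
  NumericVector t;
  Recorder(long n_steps, int stride_, int n_nodes_)
      : stride(stride_), n_nodes(n_nodes_), count(0) {
    n_rec = (int)(n_steps / stride) + 1;
    v = NumericMatrix(n_rec, n_nodes);
    t = NumericVector(n_rec);
  }
  void snap(double time, const std::vector<double>& vv) {
    if (count >= n_rec) return;
    for (int i = 0; i < n_nodes; ++i) v(count, i) = vv[i];
    t[count] = time;
    ++count;
  }
};

static inline double stim_now(double t, double cl, double dur) {
  double phase = t - std::floor(t / cl) * cl;
  return (phase < dur) ? 1.0 : 0.0;
}

// Discrete cellular strand model (Kirchhoff current balance on a chain of
// subcellular nodes). An intercellular link carries the gap-junction
// resistance R_j = 1/(beta * g_jo * g_j(Vj)), expressed as the link
// conductivity dx/(R_j * A_cell); it replaces one dx segment of the chain,
// so each cell contributes n_div - 1 myoplasmic links plus one junction link.
// Units: mm, ms, mV, mS/mm, uA/mm^2, uF/mm^2; g_jo in mS, A_cell in mm^2.
// [[Rcpp::export]]
List sim_cm_cpp(int n_cells, int n_div, double dx, double sigma_c,
                double A_cell, double beta, double g_jo, int regime,
                NumericVector gjp, double Am, double Cm, double dt,
                double t_end, double stim_amp, double stim_dur, double cl,
                bool stim_right, double out_dt, NumericVector v0,
                NumericMatrix w0) {
  FtzGuard ftz;
  const int N = n_cells * n_div + 1;
  const int n_links = N - 1;
  if (v0.size() != N) stop("v0 must have %d entries", N);
  if (w0.nrow() != 7 || w0.ncol() != N) stop("w0 must be 7 x %d", N);

  lr1::RateTab tab;
  std::vector<double> v(v0.begin(), v0.end()), vn(N);
  std::vector<double> w(7 * N);
  for (int i = 0; i < N; ++i)
    for (int g = 0; g < 7; ++g) w[7 * i + g] = w0(g, i);

  // junction links: 0-based index l = k*n_div - 1, k = 1..n_cells-1
  const int n_junc = n_cells - 1;
  std::vector<int> jlink(n_junc);
  for (int k = 1; k <= n_junc; ++k) jlink[k - 1] = k * n_div - 1;

  std::vector<double> sig(n_links, sigma_c);
  auto junc_sigma = [&](double g) {
    double sgap = dx * beta * g_jo * g / A_cell;  // dx/(R_j A_cell)
    return (sgap > 0.0) ? sgap : 0.0;
  };
  if (regime == 0)
    for (int k = 0; k < n_junc; ++k) sig[jlink[k]] = junc_sigma(1.0);

  const double inv_AmCm = 1.0 / (Am * Cm);
  const double idx2 = 1.0 / (dx * dx);
  const double stim_scale = stim_amp / (0.5 * dx * Am * Cm);  // mV/ms at node
  const int stim_node = stim_right ? N - 1 : 0;
  const long n_steps = (long)std::ceil(t_end / dt);
  const int stride = std::max(1, (int)std::lround(out_dt / dt));
  Recorder rec(n_steps, stride, N);
  rec.snap(0.0, v);

  std::vector<double> esi(N);
  for (long it = 0; it < n_steps; ++it) {
    double t = it * dt;
    if (it % 16 == 0)
      for (int i = 0; i < N; ++i) esi[i] = lr1::esi_of(w[7 * i + 6]);
    if (regime != 0) {
      for (int k = 0; k < n_junc; ++k) {
        int l = jlink[k];
        int iL = l - n_div + 1, iR = l + n_div;
        double vj = v[iR] - v[iL];
        sig[l] = junc_sigma(gj_eval(regime, vj, REAL(gjp)));
      }
    }
    double st = stim_now(t, cl, stim_dur) * stim_scale;
    int bad = -1;
    for (int i = 0; i < N; ++i) {
      double lap;
      if (i == 0)
        lap = 2.0 * sig[0] * (v[1] - v[0]) * idx2;
      else if (i == N - 1)
        lap = 2.0 * sig[n_links - 1] * (v[N - 2] - v[N - 1]) * idx2;
      else
        lap = (sig[i] * (v[i + 1] - v[i]) + sig[i - 1] * (v[i - 1] - v[i])) * idx2;
      double Iion = lr1::node_membrane(tab, v[i], &w[7 * i], dt, esi[i]);
      double dvdt = lap * inv_AmCm - 0.01 * Iion / Cm;
      if (i == stim_node) dvdt += st;
      vn[i] = v[i] + dt * dvdt;
      if (!std::isfinite(vn[i]) && bad < 0) bad = i;
    }
    if (bad >= 0)
      stop("cellular solver diverged at node %d, t = %f ms", bad + 1, t);
    v.swap(vn);
    if ((it + 1) % stride == 0) rec.snap((it + 1) * dt, v);
  }

  NumericVector x(N), vfin(N);
  for (int i = 0; i < N; ++i) { x[i] = i * dx; vfin[i] = v[i]; }
  NumericMatrix wfin(7, N);
  for (int i = 0; i < N; ++i)
    for (int g = 0; g < 7; ++g) wfin(g, i) = w[7 * i + g];
  return List::create(_["time"] = rec.t[Range(0, rec.count - 1)],
                      _["x"] = x,
                      _["v"] = rec.v(Range(0, rec.count - 1), _),
                      _["v_final"] = vfin, _["w_final"] = wfin);
}

// Homogenized 1-D cable, P1 Galerkin elements. The effective conductivity is
// either constant (linear model) or looked up per element from a tabulated
// sigma(y) on a uniform gradient grid, with the gradient lagged one step
// (fully explicit update). The capacitive term uses the consistent mass
// matrix (tridiagonal solve, factorized once) unless `lumped` is set; the
// ionic reaction is evaluated nodally so the mass solve applies to the
// diffusion/stimulus flux only.
// [[Rcpp::export]]
List sim_continuum_cpp(int n_nodes, double h, bool const_sigma,
                       double sigma_const, double y0, double dy,
                       NumericVector sig_tab, double Am, double Cm, double dt,
                       double t_end, double stim_amp, double stim_dur,
                       double cl, bool stim_right, double out_dt,
                       NumericVector v0, NumericMatrix w0, bool lumped,
                       bool grad_recovery) {
  FtzGuard ftz;
  const int N = n_nodes;
  if (v0.size() != N) stop("v0 must have %d entries", N);
  if (w0.nrow() != 7 || w0.ncol() != N) stop("w0 must be 7 x %d", N);
  const int n_el = N - 1;
  const int n_tab = sig_tab.size();
  const double* stab = REAL(sig_tab);
  const double inv_dy = (dy > 0) ? 1.0 / dy : 0.0;

  lr1::RateTab tab;
  std::vector<double> v(v0.begin(), v0.end()), vn(N), q(n_el);
  std::vector<double> w(7 * N);
  for (int i = 0; i < N; ++i)
    for (int g = 0; g < 7; ++g) w[7 * i + g] = w0(g, i);

  auto sigma_of = [&](double y) {
    if (const_sigma) return sigma_const;
    double u = (y - y0) * inv_dy;
    if (u <= 0.0) return stab[0];
    if (u >= n_tab - 1) return stab[n_tab - 1];
    int k = (int)u;
    double frac = u - k;
    return stab[k] + frac * (stab[k + 1] - stab[k]);
  };

  const double inv_AmCm = 1.0 / (Am * Cm);
  const double inv_h = 1.0 / h;
  const int stim_node = stim_right ? N - 1 : 0;
  const long n_steps = (long)std::ceil(t_end / dt);
  const int stride = std::max(1, (int)std::lround(out_dt / dt));
  Recorder rec(n_steps, stride, N);
  rec.snap(0.0, v);

  // consistent P1 mass matrix, factorized once (Thomas algorithm):
  // rows (h/3, h/6) | (h/6, 2h/3, h/6) | (h/6, h/3)
  std::vector<double> cp(N), mfac(N);
  if (!lumped) {
    double a = h / 6.0;
    double b_end = h / 3.0, b_int = 2.0 * h / 3.0;
    cp[0] = a / b_end;
    mfac[0] = 1.0 / b_end;
    for (int i = 1; i < N; ++i) {
      double b = (i == N - 1) ? b_end : b_int;
      mfac[i] = 1.0 / (b - a * cp[i - 1]);
      cp[i] = a * mfac[i];
    }
  }
  std::vector<double> r(N), z(N), esi(N);

  for (long it = 0; it < n_steps; ++it) {
    double t = it * dt;
    if (it % 16 == 0)
      for (int i = 0; i < N; ++i) esi[i] = lr1::esi_of(w[7 * i + 6]);
    for (int e = 0; e < n_el; ++e) {
      double y = (v[e + 1] - v[e]) * inv_h;
      double ys = y;
      if (grad_recovery) {
        // conductivity argument: recovered gradient (average of the nodal
        // central-difference gradients at the element ends); same continuum
        // limit as the raw element gradient but the coarse-mesh wavefront
        // is sampled over more than a single steep element
        double yl = (e > 0) ? (v[e + 1] - v[e - 1]) * 0.5 * inv_h : y;
        double yr = (e + 2 <= n_el) ? (v[e + 2] - v[e]) * 0.5 * inv_h : y;
        ys = 0.5 * (yl + yr);
      }
      q[e] = sigma_of(ys) * y;
    }
    double st = stim_now(t, cl, stim_dur) * stim_amp;
    // flux residual (load vector): boundary stimulus enters as Neumann flux
    r[0] = q[0];
    for (int i = 1; i < N - 1; ++i) r[i] = q[i] - q[i - 1];
    r[N - 1] = -q[n_el - 1];
    r[stim_node] += st;
    if (lumped) {
      z[0] = r[0] / (0.5 * h);
      for (int i = 1; i < N - 1; ++i) z[i] = r[i] * inv_h;
      z[N - 1] = r[N - 1] / (0.5 * h);
    } else {
      double a = h / 6.0;
      z[0] = r[0] * mfac[0];
      for (int i = 1; i < N; ++i) z[i] = (r[i] - a * z[i - 1]) * mfac[i];
      for (int i = N - 2; i >= 0; --i) z[i] -= cp[i] * z[i + 1];
    }
    int bad = -1;
    for (int i = 0; i < N; ++i) {
      double Iion = lr1::node_membrane(tab, v[i], &w[7 * i], dt, esi[i]);
      vn[i] = v[i] + dt * (z[i] * inv_AmCm - 0.01 * Iion / Cm);
      if (!std::isfinite(vn[i]) && bad < 0) bad = i;
    }
    if (bad >= 0)
      stop("continuum solver diverged at node %d, t = %f ms", bad + 1, t);
    v.swap(vn);
    if ((it + 1) % stride == 0) rec.snap((it + 1) * dt, v);
  }

  NumericVector x(N), vfin(N);
  for (int i = 0; i < N; ++i) { x[i] = i * h; vfin[i] = v[i]; }
  NumericMatrix wfin(7, N);
  for (int i = 0; i < N; ++i)
    for (int g = 0; g < 7; ++g) wfin(g, i) = w[7 * i + g];
  return List::create(_["time"] = rec.t[Range(0, rec.count - 1)],
                      _["x"] = x,
                      _["v"] = rec.v(Range(0, rec.count - 1), _),
                      _["v_final"] = vfin, _["w_final"] = wfin);
}
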