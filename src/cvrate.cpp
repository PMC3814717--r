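// Core numerical kernels: counter-based RNG, Monte-Carlo simulators for
// uncoupled populations and sparse E-I networks, and threshold-integration
// solvers for the stationary, first-passage, spectral and linear-response
// problems of the Fokker-Planck equation of integrate-and-fire neurons.
//
// Units throughout: membrane potential mV, time ms, rates 1/ms (kHz).

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;
typedef std::complex<double> cplx;

// ---------------------------------------------------------------------------
// Counter-based RNG: one xoshiro256++ stream per neuron, seeded with
// splitmix64(seed, stream). Stream index = neuron index, so enlarging the
// population leaves existing neurons' noise unchanged.
// ---------------------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];
  double spare;
  bool has_spare;

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t master, uint64_t stream) {
    uint64_t x = master ^ (0xD1B54A32D192ED03ULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    has_spare = false;
    spare = 0.0;
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() { // Marsaglia polar, cached spare
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

// ---------------------------------------------------------------------------
// Membrane drift f(V) in mV (per membrane time constant) for the three models
// kind: 0 = LIF, 1 = QIF, 2 = EIF
// ---------------------------------------------------------------------------

static inline double drift_f(int kind, double v, double e_l, double v_t,
                             double delta_t) {
  switch (kind) {
  case 0: return -(v - e_l);
  case 1: return v * (v - v_t) / delta_t;
  default: {
    double ex = (v - v_t) / delta_t;
    if (ex > 60.0) ex = 60.0; // cap: beyond this the spike test fires anyway
    return -(v - e_l) + delta_t * std::exp(ex);
  }
  }
}

// [[Rcpp::export]]
NumericVector drift_f_cpp(int kind, NumericVector v, double e_l, double v_t,
                          double delta_t) {
  int n = v.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = drift_f(kind, v[i], e_l, v_t, delta_t);
  return out;
}

// [[Rcpp::export]]
NumericMatrix noise_increments_cpp(int n_neurons, int n_steps, double dt,
                                   double seed) {
  NumericMatrix out(n_neurons, n_steps);
  double sq = std::sqrt(dt);
  for (int i = 0; i < n_neurons; ++i) {
    Xoshiro rng;
    rng.seed((uint64_t)seed, (uint64_t)i);
    for (int k = 0; k < n_steps; ++k) out(i, k) = sq * rng.norm();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Uncoupled population, Euler-Maruyama.
// i0, sigma sampled on the step grid (length n_steps).
// Noise term per step: sigma * sqrt(dt / tau_m) * z  (so that the input
// current reads I0 + sigma * sqrt(tau_m) * eta with <eta eta'> = delta).
// spike_delay_steps / post_hold_steps implement the deterministic traversal
// time of the tails |V| > V_ceiling cut off for the QIF (0 for LIF/EIF).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List simulate_population_cpp(int kind, double e_l, double v_t, double delta_t,
                             double tau_m, double tau_ref, double v_ceiling,
                             double v_reset, double v_floor,
                             NumericVector i0, NumericVector sigma,
                             int n_neurons, double dt, double seed,
                             double v0, int spike_delay_steps,
                             int post_hold_steps) {
  int n_steps = i0.size();
  int ref_steps = (int)std::lround(tau_ref / dt) + post_hold_steps;
  std::vector<double> times;
  std::vector<int> ids;
  times.reserve(n_neurons * 64);
  ids.reserve(n_neurons * 64);
  double sqdt_tau = std::sqrt(dt / tau_m);
  // discrete monitoring of a diffusion against a hard absorbing barrier
  // misses within-step excursions; the Broadie-Glasserman-Kou continuity
  // correction lowers the barrier by 0.5826 * (per-step noise sd).
  // Only the LIF has a hard threshold; QIF/EIF spikes are drift-dominated.
  bool hard = kind == 0;

  for (int i = 0; i < n_neurons; ++i) {
    Xoshiro rng;
    rng.seed((uint64_t)seed, (uint64_t)i);
    double v = v0;
    int hold = 0;
    for (int k = 0; k < n_steps; ++k) {
      if (hold > 0) { --hold; continue; }
      // Heun (trapezoidal) drift update with additive Euler-Maruyama noise:
      // removes the first-order bias of the forward-Euler drift on the
      // stiff, convex QIF/EIF nonlinearity
      double h1 = (drift_f(kind, v, e_l, v_t, delta_t) + i0[k]) / tau_m;
      double vp = v + h1 * dt;
      double h2 = vp >= v_ceiling ? h1 :
        (drift_f(kind, vp, e_l, v_t, delta_t) + i0[k]) / tau_m;
      double v_old = v;
      v += 0.5 * (h1 + h2) * dt + sigma[k] * sqdt_tau * rng.norm();
      if (!std::isfinite(v))
        stop("non-finite membrane potential (dt too large?) at step %d", k);
      double v_eff = hard ? v_ceiling - 0.5826 * sigma[k] * sqdt_tau
                          : v_ceiling;
      if (v >= v_eff) {
        // linear interpolation of the crossing time within the step; the
        // sub-step remainder is carried into the post-reset drift so ISIs
        // are unbiased to O(dt^2)
        double frac = (v_eff - v_old) / (v - v_old);
        times.push_back((k + frac + spike_delay_steps) * dt);
        ids.push_back(i);
        double carry = (1.0 - frac) * dt;
        v = v_reset +
          carry * (drift_f(kind, v_reset, e_l, v_t, delta_t) + i0[k]) / tau_m;
        hold = ref_steps;
      } else if (v < v_floor) {
        v = v_floor;
      }
    }
  }
  return List::create(_["time_ms"] = wrap(times), _["neuron"] = wrap(ids));
}

// ---------------------------------------------------------------------------
// Sparse E-I network with instantaneous (delta) synapses; a presynaptic spike
// at step k augments each postsynaptic potential at step k + 1.
// Neurons 0..n_e-1 excitatory, n_e..n_e+n_i-1 inhibitory.
// conn: concatenated postsynaptic target lists, offsets[i]..offsets[i+1]-1
// for presynaptic neuron i.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List simulate_network_cpp(int kind, double e_l, double v_t, double delta_t,
                          double tau_m, double tau_ref, double v_ceiling,
                          double v_reset, double v_floor,
                          int n_e, int n_i,
                          IntegerVector offsets, IntegerVector targets,
                          double j_ee, double j_ie, double j_ei, double j_ii,
                          double mu_x, double sigma_x,
                          double duration, double dt, double seed,
                          int spike_delay_steps, int post_hold_steps,
                          double abort_rate_khz) {
  int n = n_e + n_i;
  int n_steps = (int)std::lround(duration / dt);
  int ref_steps = (int)std::lround(tau_ref / dt) + post_hold_steps;
  double sqdt_tau = std::sqrt(dt / tau_m);
  double v_eff = kind == 0 ? v_ceiling - 0.5826 * sigma_x * sqdt_tau
                           : v_ceiling; // see simulate_population_cpp

  std::vector<Xoshiro> rng(n);
  std::vector<double> v(n, v_reset);
  std::vector<int> hold(n, 0);
  std::vector<double> pending(n, 0.0), pending_next(n, 0.0);
  for (int i = 0; i < n; ++i) {
    rng[i].seed((uint64_t)seed, (uint64_t)i);
    // de-synchronise initial conditions
    v[i] = v_reset + (v_ceiling - v_reset) * 0.5 * rng[i].unif();
    if (kind == 1) v[i] = v_reset < -100 ? -50.0 + 60.0 * rng[i].unif() : v[i];
  }

  std::vector<double> times; std::vector<int> ids;
  times.reserve(1 << 16); ids.reserve(1 << 16);
  int window = std::max(1, (int)std::lround(10.0 / dt));
  long spikes_in_window = 0; int win_count = 0;
  bool aborted = false;

  for (int k = 0; k < n_steps && !aborted; ++k) {
    std::swap(pending, pending_next);
    std::fill(pending_next.begin(), pending_next.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      if (hold[i] > 0) { --hold[i]; continue; }
      double vi = v[i] + pending[i];
      double h1 = (drift_f(kind, vi, e_l, v_t, delta_t) + mu_x) / tau_m;
      double vp = vi + h1 * dt;
      double h2 = vp >= v_ceiling ? h1 :
        (drift_f(kind, vp, e_l, v_t, delta_t) + mu_x) / tau_m;
      double v_old = vi;
      vi += 0.5 * (h1 + h2) * dt + sigma_x * sqdt_tau * rng[i].norm();
      if (!std::isfinite(vi)) stop("non-finite membrane potential at step %d", k);
      if (vi >= v_eff) {
        double frac = (v_eff - v_old) / (vi - v_old);
        times.push_back((k + frac + spike_delay_steps) * dt);
        ids.push_back(i);
        ++spikes_in_window;
        double carry = (1.0 - frac) * dt;
        vi = v_reset +
          carry * (drift_f(kind, v_reset, e_l, v_t, delta_t) + mu_x) / tau_m;
        hold[i] = ref_steps;
        bool pre_exc = i < n_e;
        for (int e = offsets[i]; e < offsets[i + 1]; ++e) {
          int post = targets[e];
          double j;
          if (pre_exc) j = post < n_e ? j_ee : j_ie;
          else         j = post < n_e ? -j_ei : -j_ii;
          pending_next[post] += j;
        }
      } else if (vi < v_floor) {
        vi = v_floor;
      }
      v[i] = vi;
    }
    if (++win_count == window) {
      double rate = (double)spikes_in_window / n / (window * dt); // kHz
      if (rate > abort_rate_khz) aborted = true;
      spikes_in_window = 0; win_count = 0;
    }
  }
  return List::create(_["time_ms"] = wrap(times), _["neuron"] = wrap(ids),
                      _["aborted"] = aborted);
}

// ---------------------------------------------------------------------------
// Threshold integration (downward sweep from the absorbing boundary) for the
// stationary Fokker-Planck problem. Exponential (Scharfetter-Gummel-type)
// per-cell updates keep the recursion stable at large drift/diffusion ratios.
//
// grid v ascending, uniform spacing; h = (f(V) + mu) / tau_m on the grid
// [mV/ms]; D = sigma^2 / (2 tau_m) [mV^2/ms]; i_reset = 0-based index of
// V_reset on the grid. Returns the density for unit threshold flux.
// ---------------------------------------------------------------------------

static inline double e_ratio(double x) {
  // (1 - exp(-x)) / x, stable near 0
  if (std::fabs(x) < 1e-8) return 1.0 - 0.5 * x;
  return -std::expm1(-x) / x;
}

// Exponentially-weighted cell integrals: with u measured downward from the
// upper cell edge, I_m = int_0^dv u^m exp(-beta u) du, computed stably for
// any sign/magnitude of beta * dv.
static void exp_cell_integrals(double beta, double dv, double *I0, double *I1,
                               double *I2) {
  double x = beta * dv;
  if (std::fabs(x) < 1e-4) {
    // series in x
    *I0 = dv * (1.0 - x / 2 + x * x / 6);
    *I1 = dv * dv * (0.5 - x / 3 + x * x / 8);
    *I2 = dv * dv * dv * (1.0 / 3 - x / 4 + x * x / 10);
  } else {
    double em = std::exp(-x);
    *I0 = (1.0 - em) / beta;
    *I1 = (1.0 - em * (1.0 + x)) / (beta * beta);
    *I2 = (2.0 - em * (x * x + 2.0 * x + 2.0)) / (beta * beta * beta);
  }
}

// [[Rcpp::export]]
List fp_steady_cpp(NumericVector v, NumericVector h, double D, int i_reset,
                   double tau_ref, double p_top) {
  int n = v.size();
  double dv = v[1] - v[0];
  NumericVector p(n), j(n);
  p[n - 1] = p_top;
  j[n - 1] = 1.0;
  for (int k = n - 2; k >= 0; --k) {
    double jc = (k >= i_reset) ? 1.0 : 0.0; // flux jump at reset (reinjection)
    double dS = 0.5 * (h[k] + h[k + 1]) / D * dv; // exact for linear h
    double c = jc / D;
    // p' = a(V) p - c integrated from v[k+1] down to v[k]; within the cell
    // the exponent is quadratic, handled to second order (see
    // exp_cell_integrals)
    double beta = h[k] / D;
    double gamma = 0.5 * (h[k + 1] - h[k]) / (dv * D);
    double I0, I1, I2;
    exp_cell_integrals(beta, dv, &I0, &I1, &I2);
    p[k] = p[k + 1] * std::exp(-dS) + c * (I0 - gamma * I2);
    if (p[k] < 0) p[k] = 0.0; // guard against round-off undershoot
    j[k] = jc;
  }
  // trapezoid mass for unit flux
  double mass = 0.0;
  for (int k = 0; k < n - 1; ++k) mass += 0.5 * (p[k] + p[k + 1]) * dv;
  return List::create(_["p"] = p, _["j"] = j, _["mass"] = mass);
}

// ---------------------------------------------------------------------------
// First-passage-time moments T1, T2 from x0 (absorbing top, reflecting
// bottom), via stable exponentially-weighted recursions. Returns T1, T2 on
// the whole grid (evaluate at the reset index for the ISI moments).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List fpt_moments_cpp(NumericVector v, NumericVector h, double D) {
  int n = v.size();
  double dv = v[1] - v[0];
  std::vector<double> g1(n, 0.0);
  // dS = integral of h/D across a cell (exact for linear h)
  std::vector<double> dS(n - 1);
  for (int k = 0; k < n - 1; ++k) dS[k] = 0.5 * (h[k] + h[k + 1]) / D * dv;
  // G1(y) = int_a^y exp(S(z)-S(y)) dz, upward recursion. Within a cell S is
  // quadratic; writing S(z) - S(k+1) = -beta u + gamma u^2 (u = distance
  // below the upper edge) and expanding exp(gamma u^2) to first order gives
  // a second-order accurate cell integral even at large drift/diffusion.
  for (int k = 0; k < n - 1; ++k) {
    double beta = h[k + 1] / D;
    double gamma = 0.5 * (h[k + 1] - h[k]) / (dv * D);
    double I0, I1, I2;
    exp_cell_integrals(beta, dv, &I0, &I1, &I2);
    g1[k + 1] = g1[k] * std::exp(-dS[k]) + (I0 + gamma * I2);
  }
  NumericVector t1(n), t2(n);
  t1[n - 1] = 0.0;
  for (int k = n - 2; k >= 0; --k)
    t1[k] = t1[k + 1] + 0.5 * (g1[k] + g1[k + 1]) * dv / D;
  std::vector<double> g2(n, 0.0);
  for (int k = 0; k < n - 1; ++k) {
    double beta = h[k + 1] / D;
    double gamma = 0.5 * (h[k + 1] - h[k]) / (dv * D);
    double I0, I1, I2;
    exp_cell_integrals(beta, dv, &I0, &I1, &I2);
    double w_top = 2.0 * t1[k + 1];
    double w_slope = 2.0 * (t1[k + 1] - t1[k]) / dv; // w(u) = w_top - w' u
    g2[k + 1] = g2[k] * std::exp(-dS[k]) +
      w_top * (I0 + gamma * I2) - w_slope * I1;
  }
  t2[n - 1] = 0.0;
  for (int k = n - 2; k >= 0; --k)
    t2[k] = t2[k + 1] + 0.5 * (g2[k] + g2[k + 1]) * dv / D;
  return List::create(_["t1"] = t1, _["t2"] = t2);
}

// ---------------------------------------------------------------------------
// Complex downward sweep shared by the eigenvalue characteristic equation
// (lambda = eigenvalue candidate, j_top = 1, mu_hat = 0) and the linear
// response (lambda = i omega; two sweeps: j_top = 1 / mu_hat = 0 and
// j_top = 0 / mu_hat = 1). p0 is the normalized stationary density (only
// used when mu_hat != 0). Returns the flux at the lower boundary; the
// characteristic equation is j_bottom(lambda) = 0.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
ComplexVector fp_complex_sweep_cpp(NumericVector v, NumericVector h, double D,
                                   NumericVector p0, double tau_m,
                                   int i_reset, double tau_ref,
                                   double lambda_re, double lambda_im,
                                   double j_top, double mu_hat,
                                   double p_top_scale) {
  int n = v.size();
  double dv = v[1] - v[0];
  cplx lambda(lambda_re, lambda_im);
  cplx jj(j_top, 0.0);
  // top boundary density: p = j / h for models with the threshold at
  // infinity (drift-dominated tail), 0 for a hard threshold
  cplx p = jj * p_top_scale;
  cplx reinject = std::exp(-lambda * tau_ref) * jj;
  for (int k = n - 2; k >= 0; --k) {
    if (k + 1 == i_reset) jj -= reinject; // flux discontinuity at V_reset
    double dS = 0.5 * (h[k] + h[k + 1]) / D * dv;
    cplx c = (jj - mu_hat * 0.5 * (p0[k] + p0[k + 1]) / tau_m) / D;
    double beta = h[k] / D;
    double gamma = 0.5 * (h[k + 1] - h[k]) / (dv * D);
    double I0, I1, I2;
    exp_cell_integrals(beta, dv, &I0, &I1, &I2);
    double cell = I0 - gamma * I2;
    double hom = std::exp(-dS);
    // predictor-corrector on the coupled (p, j) pair: j varies within the
    // cell (dj/dV = -lambda p), so refresh the source once from the
    // predicted lower-edge flux
    cplx p_new = p * hom + c * cell;
    cplx j_lo = jj + lambda * 0.5 * (p + p_new) * dv;
    cplx c2 = (0.5 * (jj + j_lo) -
               mu_hat * 0.5 * (p0[k] + p0[k + 1]) / tau_m) / D;
    p_new = p * hom + c2 * cell;
    jj += lambda * 0.5 * (p + p_new) * dv;
    p = p_new;
  }
  if (i_reset == 0) jj -= reinject;
  ComplexVector out(1);
  out[0].r = jj.real();
  out[0].i = jj.imag();
  return out;
}

// ---------------------------------------------------------------------------
// Method-of-lines transient oracle: Crank-Nicolson integration of the full
// Fokker-Planck PDE with Scharfetter-Gummel fluxes and delayed reinjection
// of the threshold flux at the reset potential. Independent of the spectral
// solvers; used to validate eigenvalues and step responses.
// Returns the firing rate r(t) [kHz] on the step grid.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector fp_pde_cpp(NumericVector v, NumericVector h, double D,
                         int i_reset, int ref_steps, double dt, int n_steps,
                         NumericVector p_init, double r_init, int be_steps) {
  int n = v.size();        // nodes; top node (absorbing) excluded from state
  int m = n - 1;           // unknowns 0..m-1
  double dv = v[1] - v[0];
  if (ref_steps < 1) ref_steps = 1; // reinjection applied next step at least

  // Scharfetter-Gummel face coefficients: face k between nodes k and k+1:
  // J_k = A[k] * p_k - B[k] * p_{k+1}
  std::vector<double> A(n - 1), B(n - 1);
  for (int k = 0; k < n - 1; ++k) {
    double hf = 0.5 * (h[k] + h[k + 1]);
    double x = hf * dv / D;
    if (std::fabs(x) < 1e-10) {
      A[k] = 0.5 * hf + D / dv;
      B[k] = -0.5 * hf + D / dv;
    } else {
      A[k] = hf / (1.0 - std::exp(-x));
      B[k] = hf / (std::exp(x) - 1.0);
    }
  }
  // tridiagonal L: dp_k/dt = (J_{k-1} - J_k)/dv (faces -1 and top handled
  // by zero-flux bottom and absorbing top with p_top = 0)
  std::vector<double> dl(m, 0.0), dd(m, 0.0), du(m, 0.0);
  for (int k = 0; k < m; ++k) {
    if (k > 0) { dl[k] = A[k - 1] / dv; dd[k] -= B[k - 1] / dv; }
    dd[k] -= A[k] / dv;
    if (k < m - 1) du[k] = B[k] / dv;
    // top face of node m-1 uses p_top = 0: only the A term, already added
  }
  // Crank-Nicolson matrices: M1 = I - dt/2 L (solve), M2 = I + dt/2 L.
  // The first `be_steps` steps use backward Euler (theta = 1) to damp the
  // non-dissipative Crank-Nicolson ringing excited by the initial shock.
  std::vector<double> l1(m), d1(m), u1(m), l1b(m), d1b(m), u1b(m);
  for (int k = 0; k < m; ++k) {
    l1[k] = -0.5 * dt * dl[k];
    d1[k] = 1.0 - 0.5 * dt * dd[k];
    u1[k] = -0.5 * dt * du[k];
    l1b[k] = -dt * dl[k];
    d1b[k] = 1.0 - dt * dd[k];
    u1b[k] = -dt * du[k];
  }
  std::vector<double> p(m), rhs(m), cp(m);
  for (int k = 0; k < m; ++k) p[k] = p_init[k];
  std::vector<double> rhist(ref_steps, r_init);
  int hpos = 0;
  NumericVector rout(n_steps);

  for (int s = 0; s < n_steps; ++s) {
    bool be = s < be_steps;
    const std::vector<double> &L1 = be ? l1b : l1;
    const std::vector<double> &D1 = be ? d1b : d1;
    const std::vector<double> &U1 = be ? u1b : u1;
    double r_delayed = rhist[hpos];
    // rhs = (I + dt/2 L) p + dt * source  (backward Euler: rhs = p + src)
    for (int k = 0; k < m; ++k) {
      if (be) { rhs[k] = p[k]; continue; }
      double lp = dd[k] * p[k];
      if (k > 0) lp += dl[k] * p[k - 1];
      if (k < m - 1) lp += du[k] * p[k + 1];
      rhs[k] = p[k] + 0.5 * dt * lp;
    }
    rhs[i_reset] += dt * r_delayed / dv;
    // Thomas solve
    cp[0] = U1[0] / D1[0];
    rhs[0] = rhs[0] / D1[0];
    for (int k = 1; k < m; ++k) {
      double w = D1[k] - L1[k] * cp[k - 1];
      cp[k] = k < m - 1 ? U1[k] / w : 0.0;
      rhs[k] = (rhs[k] - L1[k] * rhs[k - 1]) / w;
    }
    p[m - 1] = rhs[m - 1];
    for (int k = m - 2; k >= 0; --k) p[k] = rhs[k] - cp[k] * p[k + 1];
    double r_now = A[n - 2] * p[m - 1] / 1.0; // flux through the top face
    rout[s] = r_now;
    rhist[hpos] = r_now;
    hpos = (hpos + 1) % ref_steps;
  }
  return rout;
}

// ---------------------------------------------------------------------------
// Two-unit complex rate network integrator: per step, bilinear lookup of
// (r_inf, CV) from the operating table at the instantaneous drives, lambda
// from the universal fit, exact exponential update of the linear complex
// ODE. Returns an error time (>= 0) if the drive leaves the table hull.
// ---------------------------------------------------------------------------

static inline bool bilin2(const NumericVector &xg, const NumericVector &yg,
                          const NumericMatrix &z, double x, double y,
                          double *out) {
  int nx = xg.size(), ny = yg.size();
  if (x < xg[0] || x > xg[nx - 1] || y < yg[0] || y > yg[ny - 1]) return false;
  int i = std::upper_bound(xg.begin(), xg.end(), x) - xg.begin() - 1;
  int j = std::upper_bound(yg.begin(), yg.end(), y) - yg.begin() - 1;
  if (i > nx - 2) i = nx - 2;
  if (j > ny - 2) j = ny - 2;
  if (i < 0) i = 0;
  if (j < 0) j = 0;
  double tx = (x - xg[i]) / (xg[i + 1] - xg[i]);
  double ty = (y - yg[j]) / (yg[j + 1] - yg[j]);
  *out = (1 - tx) * (1 - ty) * z(i, j) + tx * (1 - ty) * z(i + 1, j) +
         (1 - tx) * ty * z(i, j + 1) + tx * ty * z(i + 1, j + 1);
  return true;
}

// [[Rcpp::export]]
List rate_network_cpp(NumericVector mu_grid, NumericVector sigma_grid,
                      NumericMatrix rate_mat, NumericMatrix cv_mat,
                      double mu_x, double s2_x,
                      NumericVector me, NumericVector mi,
                      NumericVector se, NumericVector si,
                      double re_coef, double im_coef, double cv_floor,
                      double dt, int n_steps,
                      double x_e0, double y_e0, double x_i0, double y_i0) {
  cplx re(x_e0, y_e0), ri(x_i0, y_i0);
  NumericVector oxe(n_steps), oye(n_steps), oxi(n_steps), oyi(n_steps);
  double t_err = -1.0;
  for (int s = 0; s < n_steps; ++s) {
    double rr_e = std::max(re.real(), 0.0), rr_i = std::max(ri.real(), 0.0);
    double mu_e = mu_x + me[0] * rr_e + me[1] * rr_i;
    double mu_i = mu_x + mi[0] * rr_e + mi[1] * rr_i;
    double sg_e = std::sqrt(s2_x + se[0] * rr_e + se[1] * rr_i);
    double sg_i = std::sqrt(s2_x + si[0] * rr_e + si[1] * rr_i);
    double rinf_e, rinf_i, cv_e, cv_i;
    if (!bilin2(mu_grid, sigma_grid, rate_mat, mu_e, sg_e, &rinf_e) ||
        !bilin2(mu_grid, sigma_grid, cv_mat, mu_e, sg_e, &cv_e) ||
        !bilin2(mu_grid, sigma_grid, rate_mat, mu_i, sg_i, &rinf_i) ||
        !bilin2(mu_grid, sigma_grid, cv_mat, mu_i, sg_i, &cv_i)) {
      t_err = (s + 1) * dt;
      break;
    }
    cv_e = std::max(cv_e, cv_floor);
    cv_i = std::max(cv_i, cv_floor);
    double rke = std::max(rinf_e, 1e-3) / 1000.0;
    double rki = std::max(rinf_i, 1e-3) / 1000.0;
    cplx lam_e(-2 * M_PI * re_coef * cv_e * cv_e * rke,
               2 * M_PI * im_coef * rke);
    cplx lam_i(-2 * M_PI * re_coef * cv_i * cv_i * rki,
               2 * M_PI * im_coef * rki);
    re = rinf_e + (re - cplx(rinf_e, 0)) * std::exp(lam_e * dt);
    ri = rinf_i + (ri - cplx(rinf_i, 0)) * std::exp(lam_i * dt);
    oxe[s] = re.real(); oye[s] = re.imag();
    oxi[s] = ri.real(); oyi[s] = ri.imag();
  }
  return List::create(_["x_e"] = oxe, _["y_e"] = oye, _["x_i"] = oxi,
                      _["y_i"] = oyi, _["t_err"] = t_err);
}
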