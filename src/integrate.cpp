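#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// u / (1 - exp(-u)) with the removable singularity at u = 0 filled by its limit.
static inline double phi_fun(double u) {
  if (std::fabs(u) < 1e-9) return 1.0 + u / 2.0;
  return u / (-std::expm1(-u));
}

// piecewise-linear f(v); p points at k_l,k_m,k_r,b_l,b_m,b_r,v_l,v_r
static inline double pwl_f(const double *p, double v) {
  if (v < p[6]) return p[0] * v + p[3];
  if (v < p[7]) return p[1] * v + p[4];
  return p[2] * v + p[5];
}

// Right-hand sides. Parameter packing (must match R/models.R pack_params):
//  1 qif:    v_r, v_t, v_peak, v_reset, C
//  2 fhn:    tau_w, k_w, b_w, C
//  3 bfhn:   tau_w, a, b, c, C
//  4 fhn3d:  tau_w, k_w, b_w, tau_u, k_u, b_u, C   (state v,u,w)
//  5 pwl2d:  k_l,k_m,k_r,b_l,b_m,b_r,v_l,v_r, tau_w,k_w, C
//  6 pwl3d:  k_l,k_m,k_r,b_l,b_m,b_r,v_l,v_r, tau_u,k_u, tau_w,k_w, C
//  7 hh:     C_m, g_Na, g_K, g_L, E_Na, E_K, E_L   (state V,m,h,n)
static void eval_rhs_cpp(int id, const double *p, const double *x, double ie,
                         double *dx) {
  switch (id) {
  case 1: {
    dx[0] = (x[0] - p[0]) * (x[0] - p[1]) + ie;
    break;
  }
  case 2: {
    double C = p[3];
    dx[0] = (x[0] - x[0] * x[0] * x[0] / 3.0 - x[1] + ie) / C;
    dx[1] = (p[1] * x[0] + p[2] - x[1]) / p[0];
    break;
  }
  case 3: {
    double C = p[4];
    double winf = p[1] / (1.0 + p[2] * std::exp(-x[0] / p[3]));
    dx[0] = (x[0] - x[0] * x[0] * x[0] / 3.0 - x[1] + ie) / C;
    dx[1] = (winf - x[1]) / p[0];
    break;
  }
  case 4: {
    double C = p[6];
    dx[0] = (x[0] - x[0] * x[0] * x[0] / 3.0 - x[1] - x[2] + ie) / C;
    dx[1] = (p[4] * x[0] + p[5] - x[1]) / p[3]; // u
    dx[2] = (p[1] * x[0] + p[2] - x[2]) / p[0]; // w
    break;
  }
  case 5: {
    double C = p[10];
    dx[0] = (pwl_f(p, x[0]) - x[1] + ie) / C;
    dx[1] = (p[9] * x[0] - x[1]) / p[8];
    break;
  }
  case 6: {
    double C = p[12];
    dx[0] = (pwl_f(p, x[0]) - x[1] - x[2] + ie) / C;
    dx[1] = (p[9] * x[0] - x[1]) / p[8];   // u
    dx[2] = (p[11] * x[0] - x[2]) / p[10]; // w
    break;
  }
  case 7: {
    double V = x[0], m = x[1], h = x[2], n = x[3];
    double am = phi_fun((V + 40.0) / 10.0);
    double bm = 4.0 * std::exp(-(V + 65.0) / 18.0);
    double ah = 0.07 * std::exp(-(V + 65.0) / 20.0);
    double bh = 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0));
    double an = 0.1 * phi_fun((V + 55.0) / 10.0);
    double bn = 0.125 * std::exp(-(V + 65.0) / 80.0);
    double ina = p[1] * m * m * m * h * (V - p[4]);
    double ik = p[2] * n * n * n * n * (V - p[5]);
    double il = p[3] * (V - p[6]);
    dx[0] = (ie - ina - ik - il) / p[0];
    dx[1] = am * (1.0 - m) - bm * m;
    dx[2] = ah * (1.0 - h) - bh * h;
    dx[3] = an * (1.0 - n) - bn * n;
    break;
  }
  default:
    stop("unknown model id");
  }
}

// [[Rcpp::export]]
NumericVector rhs_cpp(int model_id, NumericVector par, NumericVector state,
                      double ie) {
  NumericVector out(state.size());
  eval_rhs_cpp(model_id, par.begin(), state.begin(), ie, out.begin());
  return out;
}

static inline double stim_at(const NumericMatrix &stim, double t) {
  double amp = 0.0;
  for (int r = 0; r < stim.nrow(); ++r) {
    double t0 = stim(r, 0), t1 = stim(r, 1);
    if (t >= t0 && t < t1) {
      double a0 = stim(r, 2), a1 = stim(r, 3);
      amp += (t1 == R_PosInf || a0 == a1)
                 ? a0
                 : a0 + (a1 - a0) * (t - t0) / (t1 - t0);
    }
  }
  return amp;
}

// Fixed-step classic 4th-order Runge-Kutta.
// clamp: hold state[0] at clamp_v while the other coordinates evolve.
// backward: integrate d/dt = -f (for stable-manifold tracing; only
// time-invariant stimuli are meaningful here).
// QIF (model_id 1): when v >= v_peak the step is accepted, the peak recorded
// as min(v, reset_cap) and v reset to v_reset (spike_peak/reset events).
// [[Rcpp::export]]
List integrate_core(int model_id, NumericVector par, NumericVector state0,
                    double t0, double dt, int n_steps, NumericMatrix stim,
                    bool clamp, double clamp_v, bool backward, int store_every,
                    double reset_cap, double box_lo, double box_hi) {
  const int d = state0.size();
  std::vector<double> x(state0.begin(), state0.end());
  if (clamp) x[0] = clamp_v;
  const double dir = backward ? -1.0 : 1.0;

  std::vector<double> k1(d), k2(d), k3(d), k4(d), xt(d);
  std::vector<double> times_out, ie_out, states_out;
  std::vector<double> spike_t, spike_peak;

  double vmax = x[0], t_vmax = t0;
  int stored = 0;
  bool truncated = false, err = false;
  double err_time = NA_REAL;
  double t = t0;

  auto store = [&](double tt) {
    times_out.push_back(tt);
    ie_out.push_back(stim_at(stim, tt));
    for (int j = 0; j < d; ++j) states_out.push_back(x[j]);
    ++stored;
  };
  store(t);

  const double vpeak = (model_id == 1) ? par[2] : 0.0;
  const double vreset = (model_id == 1) ? par[3] : 0.0;

  int i = 0;
  for (i = 0; i < n_steps; ++i) {
    double ie1 = stim_at(stim, t);
    double ie2 = stim_at(stim, t + dt / 2.0);
    double ie3 = stim_at(stim, t + dt);

    eval_rhs_cpp(model_id, par.begin(), x.data(), ie1, k1.data());
    if (clamp) k1[0] = 0.0;
    for (int j = 0; j < d; ++j) xt[j] = x[j] + dir * dt / 2.0 * k1[j];
    if (clamp) xt[0] = clamp_v;
    eval_rhs_cpp(model_id, par.begin(), xt.data(), ie2, k2.data());
    if (clamp) k2[0] = 0.0;
    for (int j = 0; j < d; ++j) xt[j] = x[j] + dir * dt / 2.0 * k2[j];
    if (clamp) xt[0] = clamp_v;
    eval_rhs_cpp(model_id, par.begin(), xt.data(), ie2, k3.data());
    if (clamp) k3[0] = 0.0;
    for (int j = 0; j < d; ++j) xt[j] = x[j] + dir * dt * k3[j];
    if (clamp) xt[0] = clamp_v;
    eval_rhs_cpp(model_id, par.begin(), xt.data(), ie3, k4.data());
    if (clamp) k4[0] = 0.0;

    for (int j = 0; j < d; ++j)
      x[j] += dir * dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    if (clamp) x[0] = clamp_v;
    t += dt;

    bool finite = true;
    for (int j = 0; j < d; ++j)
      if (!std::isfinite(x[j])) finite = false;

    if (model_id == 1 && !clamp && finite && x[0] >= vpeak) {
      double peak = std::min(x[0], reset_cap);
      spike_t.push_back(t);
      spike_peak.push_back(peak);
      if (peak > vmax) { vmax = peak; t_vmax = t; }
      x[0] = vreset;
    }

    if (!finite) {
      // QIF pre-reset overshoot cannot occur (reset handled above); any
      // non-finite state is an integration failure.
      err = true;
      err_time = t;
      break;
    }

    if (x[0] > vmax) { vmax = x[0]; t_vmax = t; }

    if ((i + 1) % store_every == 0 || i == n_steps - 1) store(t);

    if (x[0] < box_lo || x[0] > box_hi) {
      truncated = true;
      if ((i + 1) % store_every != 0 && i != n_steps - 1) store(t);
      break;
    }
  }

  NumericMatrix states(stored, d);
  for (int r = 0; r < stored; ++r)
    for (int j = 0; j < d; ++j) states(r, j) = states_out[r * d + j];

  return List::create(
      _["times"] = NumericVector(times_out.begin(), times_out.end()),
      _["states"] = states,
      _["ie"] = NumericVector(ie_out.begin(), ie_out.end()),
      _["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
      _["spike_peak"] = NumericVector(spike_peak.begin(), spike_peak.end()),
      _["vmax"] = vmax, _["t_vmax"] = t_vmax,
      _["final_state"] = NumericVector(x.begin(), x.end()),
      _["n_done"] = i, _["truncated"] = truncated, _["err"] = err,
      _["err_time"] = err_time);
}
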