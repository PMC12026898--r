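#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sigmoidal f-I curve of the mean-field reduction: r = (aI - b) / (1 - exp(-d(aI - b))).
// The removable singularity at aI = b has limit 1/d.
static inline double fi_curve(double I, double a, double b, double d) {
  double x = a * I - b;
  if (std::fabs(x) < 1e-9) return 1.0 / d;
  return x / (1.0 - std::exp(-d * x));
}

// Fast explicit-seed RNG for the stochastic integrators: xoshiro256++
// seeded through splitmix64, standard normals via Box-Muller. Every
// simulation owns one generator seeded from its R-side seed argument, so
// trajectories are bit-reproducible from that integer alone.
struct SimRng {
  uint64_t s[4];
  bool has_spare = false;
  double spare = 0.0;
  explicit SimRng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1;
    do { u1 = unif(); } while (u1 <= 0.0);
    double u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

struct FicConsts {
  double a_E, b_E, d_E, a_I, b_I, d_I, tau_E, tau_I, gamma, J_NMDA, I_0, W_E, W_I;
};

static FicConsts unpack_consts(const List &cl) {
  FicConsts c;
  c.a_E = as<double>(cl["a_E"]);   c.b_E = as<double>(cl["b_E"]);
  c.d_E = as<double>(cl["d_E"]);   c.a_I = as<double>(cl["a_I"]);
  c.b_I = as<double>(cl["b_I"]);   c.d_I = as<double>(cl["d_I"]);
  c.tau_E = as<double>(cl["tau_E"]); c.tau_I = as<double>(cl["tau_I"]);
  c.gamma = as<double>(cl["gamma"]); c.J_NMDA = as<double>(cl["J_NMDA"]);
  c.I_0 = as<double>(cl["I_0"]);   c.W_E = as<double>(cl["W_E"]);
  c.W_I = as<double>(cl["W_I"]);
  return c;
}

// One deterministic drift evaluation; writes rates and gating derivatives.
static inline void drift_eval(const int n, const double *se, const double *si,
                              const NumericMatrix &sc,
                              const double *w_ee, const double *w_ei,
                              const double *w_ie, const double *w_ii,
                              double g, const FicConsts &c,
                              double *dse, double *dsi, double *re, double *ri) {
  for (int k = 0; k < n; ++k) {
    double coup = 0.0;
    for (int j = 0; j < n; ++j) coup += sc(k, j) * se[j];
    double I_E = c.W_E * c.I_0 + w_ee[k] * se[k] + g * c.J_NMDA * coup - w_ie[k] * si[k];
    double I_I = c.W_I * c.I_0 + w_ei[k] * se[k] - w_ii[k] * si[k];
    double rE = fi_curve(I_E, c.a_E, c.b_E, c.d_E);
    double rI = fi_curve(I_I, c.a_I, c.b_I, c.d_I);
    re[k] = rE;
    ri[k] = rI;
    dse[k] = -se[k] / c.tau_E + (1.0 - se[k]) * c.gamma * rE;
    dsi[k] = -si[k] / c.tau_I + rI;
  }
}

// [[Rcpp::export]]
List cpp_drift(NumericVector s_e, NumericVector s_i, NumericMatrix sc,
               NumericVector w_ee, NumericVector w_ei, NumericVector w_ie,
               NumericVector w_ii, double g, List consts) {
  int n = s_e.size();
  FicConsts c = unpack_consts(consts);
  NumericVector dse(n), dsi(n), re(n), ri(n);
  drift_eval(n, s_e.begin(), s_i.begin(), sc, w_ee.begin(), w_ei.begin(),
             w_ie.begin(), w_ii.begin(), g, c,
             dse.begin(), dsi.begin(), re.begin(), ri.begin());
  return List::create(_["ds_e"] = dse, _["ds_i"] = dsi,
                      _["r_e"] = re, _["r_i"] = ri);
}

// Euler-Maruyama integration of the coupled gating equations. States are
// stored at every step (column 0 = initial state); rates are the
// instantaneous population rates at the stored states. Noise is drawn in
// fixed region-major order (all excitatory draws for a step, then all
// inhibitory draws), so N is part of the reproducibility contract.
// [[Rcpp::export]]
List cpp_integrate_neural(NumericMatrix sc, NumericVector w_ee, NumericVector w_ei,
                          NumericVector w_ie, NumericVector w_ii,
                          NumericVector sigma, double g, List consts,
                          double dt, int n_steps,
                          NumericVector s_e0, NumericVector s_i0, bool noisy,
                          int seed) {
  int n = s_e0.size();
  FicConsts c = unpack_consts(consts);
  NumericMatrix S_E(n, n_steps + 1), S_I(n, n_steps + 1), R_E(n, n_steps + 1);
  std::vector<double> se(s_e0.begin(), s_e0.end()), si(s_i0.begin(), s_i0.end());
  std::vector<double> dse(n), dsi(n), re(n), ri(n);
  double sqdt = std::sqrt(dt);
  SimRng rng((uint64_t)seed);
  for (int t = 0; t <= n_steps; ++t) {
    drift_eval(n, se.data(), si.data(), sc, w_ee.begin(), w_ei.begin(),
               w_ie.begin(), w_ii.begin(), g, c,
               dse.data(), dsi.data(), re.data(), ri.data());
    for (int k = 0; k < n; ++k) {
      if (!std::isfinite(se[k]) || !std::isfinite(si[k]))
        stop("non-finite neural state at step %d, region %d", t, k + 1);
      S_E(k, t) = se[k];
      S_I(k, t) = si[k];
      R_E(k, t) = re[k];
    }
    if (t == n_steps) break;
    if (noisy) {
      std::vector<double> xe(n), xi(n);
      for (int k = 0; k < n; ++k) xe[k] = rng.norm();
      for (int k = 0; k < n; ++k) xi[k] = rng.norm();
      for (int k = 0; k < n; ++k) {
        se[k] += dse[k] * dt + sigma[k] * sqdt * xe[k];
        si[k] += dsi[k] * dt + sigma[k] * sqdt * xi[k];
      }
    } else {
      for (int k = 0; k < n; ++k) {
        se[k] += dse[k] * dt;
        si[k] += dsi[k] * dt;
      }
    }
    for (int k = 0; k < n; ++k) {
      se[k] = std::min(1.0, std::max(0.0, se[k]));
      si[k] = std::min(1.0, std::max(0.0, si[k]));
    }
  }
  return List::create(_["s_e"] = S_E, _["s_i"] = S_I, _["r_e"] = R_E);
}

// Fused forward scan: neural Euler-Maruyama and Balloon-Windkessel advanced
// in one pass, returning BOLD frames and post-burn-in trajectory means
// without materializing the full trajectory. Noise draws follow the exact
// order of cpp_integrate_neural, so the simulated path is identical under
// the same RNG state.
// [[Rcpp::export]]
List cpp_simulate_scan(NumericMatrix sc, NumericVector w_ee, NumericVector w_ei,
                       NumericVector w_ie, NumericVector w_ii,
                       NumericVector sigma, double g, List consts,
                       double dt, int n_steps, int burn_in_steps,
                       NumericVector s_e0, NumericVector s_i0, bool noisy,
                       int seed,
                       double tr, double kappa, double gamma_h, double tau_h,
                       double alpha, double rho, double V0,
                       double k1, double k2, double k3) {
  int n = s_e0.size();
  FicConsts c = unpack_consts(consts);
  std::vector<double> se(s_e0.begin(), s_e0.end()), si(s_i0.begin(), s_i0.end());
  std::vector<double> dse(n), dsi(n), re(n), ri(n);
  std::vector<double> sH(n, 0.0), fH(n, 1.0), vH(n, 1.0), qH(n, 1.0);
  std::vector<double> sum_r(n, 0.0), sum_se(n, 0.0), sum_si(n, 0.0);
  double post_s = (n_steps - burn_in_steps) * dt;
  int n_frames = (int)std::floor(post_s / tr + 1e-9);
  std::vector<int> frame_step(n_frames);
  for (int f = 0; f < n_frames; ++f) {
    int idx = burn_in_steps + (int)std::llround((f + 1) * tr / dt);
    frame_step[f] = std::min(idx, n_steps);
  }
  NumericMatrix bold(n, n_frames);
  int next_f = 0;
  double sqdt = std::sqrt(dt);
  double inv_alpha = 1.0 / alpha;
  SimRng rng((uint64_t)seed);
  for (int t = 0; t <= n_steps; ++t) {
    drift_eval(n, se.data(), si.data(), sc, w_ee.begin(), w_ei.begin(),
               w_ie.begin(), w_ii.begin(), g, c,
               dse.data(), dsi.data(), re.data(), ri.data());
    if (t > burn_in_steps) {
      for (int k = 0; k < n; ++k) {
        sum_r[k] += re[k]; sum_se[k] += se[k]; sum_si[k] += si[k];
      }
    }
    if (next_f < n_frames && t == frame_step[next_f]) {
      for (int k = 0; k < n; ++k) {
        bold(k, next_f) = 100.0 * V0 *
          (k1 * (1.0 - qH[k]) + k2 * (1.0 - qH[k] / vH[k]) + k3 * (1.0 - vH[k]));
      }
      ++next_f;
    }
    if (t == n_steps) break;
    // hemodynamic step driven by S_E at step t; all derivatives use the
    // pre-update hemodynamic state (same order as cpp_balloon_bold)
    for (int k = 0; k < n; ++k) {
      double fout = std::pow(vH[k], inv_alpha);
      double E_f = 1.0 - std::pow(1.0 - rho, 1.0 / fH[k]);
      double ds = se[k] - kappa * sH[k] - gamma_h * (fH[k] - 1.0);
      double df = sH[k];
      double dv = (fH[k] - fout) / tau_h;
      double dq = (fH[k] * E_f / rho - fout * qH[k] / vH[k]) / tau_h;
      sH[k] += ds * dt; fH[k] += df * dt; vH[k] += dv * dt; qH[k] += dq * dt;
      if (fH[k] < 1e-6) fH[k] = 1e-6;
      if (vH[k] < 1e-6) vH[k] = 1e-6;
      if (qH[k] < 1e-6) qH[k] = 1e-6;
      if (!std::isfinite(sH[k]) || !std::isfinite(vH[k]) || !std::isfinite(qH[k]))
        stop("non-finite hemodynamic state at step %d, region %d", t, k + 1);
    }
    // neural Euler-Maruyama step (identical draw order to cpp_integrate_neural)
    if (noisy) {
      std::vector<double> xe(n), xi(n);
      for (int k = 0; k < n; ++k) xe[k] = rng.norm();
      for (int k = 0; k < n; ++k) xi[k] = rng.norm();
      for (int k = 0; k < n; ++k) {
        se[k] += dse[k] * dt + sigma[k] * sqdt * xe[k];
        si[k] += dsi[k] * dt + sigma[k] * sqdt * xi[k];
      }
    } else {
      for (int k = 0; k < n; ++k) {
        se[k] += dse[k] * dt;
        si[k] += dsi[k] * dt;
      }
    }
    for (int k = 0; k < n; ++k) {
      se[k] = std::min(1.0, std::max(0.0, se[k]));
      si[k] = std::min(1.0, std::max(0.0, si[k]));
      if (!std::isfinite(se[k]) || !std::isfinite(si[k]))
        stop("non-finite neural state at step %d, region %d", t, k + 1);
    }
  }
  int n_post = n_steps - burn_in_steps;
  NumericVector mean_r(n), mean_se(n), mean_si(n);
  for (int k = 0; k < n; ++k) {
    mean_r[k] = sum_r[k] / n_post;
    mean_se[k] = sum_se[k] / n_post;
    mean_si[k] = sum_si[k] / n_post;
  }
  return List::create(_["bold"] = bold, _["mean_r"] = mean_r,
                      _["mean_se"] = mean_se, _["mean_si"] = mean_si);
}

// Damped fixed-point sweeps for feedback inhibition control: repeatedly
// integrate the noiseless dynamics, measure the temporal-mean excitatory
// rate over the tail of each sweep, and nudge w_IE towards the target rate.
// [[Rcpp::export]]
List cpp_calibrate_fic(NumericMatrix sc, NumericVector w_ee, NumericVector w_ei,
                       NumericVector w_ie_init, NumericVector w_ii, double g,
                       List consts, double dt, int sweep_steps,
                       double eta, double target, double tol, int max_sweeps,
                       NumericVector s_e0, NumericVector s_i0,
                       int confirm_steps) {
  int n = s_e0.size();
  FicConsts c = unpack_consts(consts);
  std::vector<double> se(s_e0.begin(), s_e0.end()), si(s_i0.begin(), s_i0.end());
  std::vector<double> dse(n), dsi(n), re(n), ri(n);
  NumericVector w_ie = clone(w_ie_init);
  NumericVector mean_r(n);
  bool converged = false;
  int sweep = 0;
  // tail-mean excitatory rate of a noiseless integration of given length
  auto run_measure = [&](int steps) {
    std::fill(mean_r.begin(), mean_r.end(), 0.0);
    int measure_from = steps / 2, n_meas = 0;
    for (int t = 0; t < steps; ++t) {
      drift_eval(n, se.data(), si.data(), sc, w_ee.begin(), w_ei.begin(),
                 w_ie.begin(), w_ii.begin(), g, c,
                 dse.data(), dsi.data(), re.data(), ri.data());
      for (int k = 0; k < n; ++k) {
        se[k] = std::min(1.0, std::max(0.0, se[k] + dse[k] * dt));
        si[k] = std::min(1.0, std::max(0.0, si[k] + dsi[k] * dt));
        if (!std::isfinite(se[k]))
          stop("non-finite state during calibration sweep %d, region %d", sweep + 1, k + 1);
      }
      if (t >= measure_from) {
        for (int k = 0; k < n; ++k) mean_r[k] += re[k];
        ++n_meas;
      }
    }
    double worst = 0.0;
    for (int k = 0; k < n; ++k) {
      mean_r[k] /= n_meas;
      worst = std::max(worst, std::fabs(mean_r[k] - target));
    }
    return worst;
  };
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    double worst = run_measure(sweep_steps);
    if (worst <= tol) {
      // a short sweep can sit on an unstable fixed point without leaving it;
      // confirm over a longer horizon before accepting, and keep iterating
      // from the escaped state otherwise
      worst = run_measure(confirm_steps);
      if (worst <= tol) { converged = true; break; }
    }
    for (int k = 0; k < n; ++k) {
      w_ie[k] += eta * (mean_r[k] - target);
      if (w_ie[k] < 1e-4) w_ie[k] = 1e-4;
    }
  }
  NumericVector resid(n);
  for (int k = 0; k < n; ++k) resid[k] = mean_r[k] - target;
  return List::create(_["w_ie"] = w_ie, _["converged"] = converged,
                      _["sweeps"] = sweep + 1, _["mean_rates"] = mean_r,
                      _["residuals"] = resid);
}

// Balloon-Windkessel hemodynamics driven by the excitatory gating variable,
// Euler-integrated at the neural step, decimated to one frame per TR after
// discarding the neural burn-in. States per region: vasodilatory signal,
// inflow, venous volume, deoxyhemoglobin.
// [[Rcpp::export]]
NumericMatrix cpp_balloon_bold(NumericMatrix s_e, double dt, int burn_in_steps,
                               double tr, double kappa, double gamma_h,
                               double tau_h, double alpha, double rho,
                               double V0, double k1, double k2, double k3) {
  int n = s_e.nrow();
  int n_store = s_e.ncol();            // n_steps + 1 states
  int n_steps = n_store - 1;
  double post_s = (n_steps - burn_in_steps) * dt;
  int n_frames = (int)std::floor(post_s / tr + 1e-9);
  std::vector<int> frame_step(n_frames);
  for (int f = 0; f < n_frames; ++f) {
    int idx = burn_in_steps + (int)std::llround((f + 1) * tr / dt);
    frame_step[f] = std::min(idx, n_steps);
  }
  NumericMatrix bold(n, n_frames);
  double inv_alpha = 1.0 / alpha;
  for (int k = 0; k < n; ++k) {
    double sH = 0.0, fH = 1.0, vH = 1.0, qH = 1.0;
    int next_f = 0;
    for (int t = 0; t <= n_steps; ++t) {
      if (next_f < n_frames && t == frame_step[next_f]) {
        bold(k, next_f) = 100.0 * V0 *
          (k1 * (1.0 - qH) + k2 * (1.0 - qH / vH) + k3 * (1.0 - vH));
        ++next_f;
      }
      if (t == n_steps) break;
      double x = s_e(k, t);
      double fout = std::pow(vH, inv_alpha);
      double E_f = 1.0 - std::pow(1.0 - rho, 1.0 / fH);
      double ds = x - kappa * sH - gamma_h * (fH - 1.0);
      double df = sH;
      double dv = (fH - fout) / tau_h;
      double dq = (fH * E_f / rho - fout * qH / vH) / tau_h;
      sH += ds * dt; fH += df * dt; vH += dv * dt; qH += dq * dt;
      if (fH < 1e-6) fH = 1e-6;
      if (vH < 1e-6) vH = 1e-6;
      if (qH < 1e-6) qH = 1e-6;
      if (!std::isfinite(sH) || !std::isfinite(vH) || !std::isfinite(qH))
        stop("non-finite hemodynamic state at step %d, region %d", t, k + 1);
    }
  }
  return bold;
}
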