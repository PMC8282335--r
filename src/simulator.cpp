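// Reduced ionic-model simulator for immature (spontaneously beating) and
// adult (stimulated) ventricular action potentials.
//
// dV/dt = -(I_Na + I_CaL + I_Kr + I_Ks + I_to + I_K1 + I_f + I_bNa)/Cm + I_stim
// integrated by Forward Euler at a small internal step, with the stochastic
// voltage update V <- V - I*dt/Cm + xi*n*sqrt(dt) (n ~ N(0,1)) applied during
// the noisy beats only.  Gate variables follow two-parameter Boltzmann
// steady states with voltage-dependent time constants.
//
// Drug schemes on I_Kr:
//   simple block:  G_Kr scaled once by (1 - block_fraction)
//   state-dependent: bound fraction b with db/dt = kon*[D]*p_open*(1-b) - koff*b,
//                    p_open = xr * r(V); multiplier (1-b) on G_Kr.

#include <Rcpp.h>
#include <cmath>
#include <random>
using namespace Rcpp;

namespace {

struct Params {
  double gna, gcal, gkr, gks, gto, gk1, gf, gbna;
  double ena, eca, ek, ef, cm;
  double tauf_amp, tauxr, tauxs, tauy;
};

inline double getp(const NumericVector& p, const char* nm) {
  if (!p.containsElementNamed(nm))
    stop("ionic parameter vector is missing element '%s'", nm);
  return p[nm];
}

Params unpack(const NumericVector& p) {
  Params q;
  q.gna = getp(p, "g_na");   q.gcal = getp(p, "g_cal");
  q.gkr = getp(p, "g_kr");   q.gks  = getp(p, "g_ks");
  q.gto = getp(p, "g_to");   q.gk1  = getp(p, "g_k1");
  q.gf  = getp(p, "g_f");    q.gbna = getp(p, "g_bna");
  q.ena = getp(p, "e_na");   q.eca  = getp(p, "e_ca");
  q.ek  = getp(p, "e_k");    q.ef   = getp(p, "e_f");
  q.cm  = getp(p, "cm");
  q.tauf_amp = getp(p, "tau_f_amp");
  q.tauxr    = getp(p, "tau_xr");
  q.tauxs    = getp(p, "tau_xs");
  q.tauy     = getp(p, "tau_y");
  return q;
}

inline double sig(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct State {
  double v, m, h, d, f, xr, xs, a, ri, y, b;
};

// steady-state initialisation of all gates at voltage v
State init_state(double v) {
  State s;
  s.v  = v;
  s.m  = sig((v + 40.0) / 6.0);
  s.h  = sig(-(v + 67.0) / 5.5);
  s.d  = sig((v + 8.0) / 6.0);
  s.f  = sig(-(v + 24.0) / 5.0);
  s.xr = sig((v + 20.0) / 8.0);
  s.xs = sig((v - 2.0) / 12.0);
  s.a  = sig((v - 5.0) / 9.0);
  s.ri = sig(-(v + 32.0) / 6.0);
  s.y  = sig(-(v + 72.0) / 7.0);
  s.b  = 0.0;
  return s;
}

// Per-voltage lookup tables for the gate updates.  For each gate the Forward
// Euler update g += dt*(ginf-g)/tau is rewritten g = A(V)*g + B(V) with
// A = 1 - dt/tau, B = dt*ginf/tau, tabulated on a 0.05 mV grid and linearly
// interpolated; k1inf and the IKr rectification factor are tabulated too.
struct Tables {
  static constexpr double vlo = -150.0, vhi = 100.0, h = 0.05;
  static constexpr int n = (int)((vhi - vlo) / h) + 1;
  std::vector<double> Am, Bm, Ah, Bh, Ad, Bd, Af, Bf, Axr, Bxr,
                      Axs, Bxs, Aa, Ba, Ari, Bri, Ay, By, k1, rkr;
  Tables(double dt, const Params& p) {
    auto rsz = [&](std::vector<double>& x) { x.resize(n); };
    rsz(Am); rsz(Bm); rsz(Ah); rsz(Bh); rsz(Ad); rsz(Bd); rsz(Af); rsz(Bf);
    rsz(Axr); rsz(Bxr); rsz(Axs); rsz(Bxs); rsz(Aa); rsz(Ba);
    rsz(Ari); rsz(Bri); rsz(Ay); rsz(By); rsz(k1); rsz(rkr);
    for (int i = 0; i < n; ++i) {
      const double v = vlo + i * h;
      auto put = [&](std::vector<double>& A, std::vector<double>& B,
                     double ginf, double tau) {
        A[i] = 1.0 - dt / tau; B[i] = dt * ginf / tau;
      };
      put(Am, Bm, sig((v + 40.0) / 6.0), 0.03 + 0.15 * sig(-(v + 48.0) / 6.0));
      put(Ah, Bh, sig(-(v + 67.0) / 5.5), 0.6 + 25.0 * sig(-(v + 40.0) / 6.0));
      put(Ad, Bd, sig((v + 8.0) / 6.0), 0.6 + 2.0 * sig(-(v + 28.0) / 6.0));
      put(Af, Bf, sig(-(v + 24.0) / 5.0),
          30.0 + p.tauf_amp * std::exp(-(v + 15.0) * (v + 15.0) / 800.0));
      put(Axr, Bxr, sig((v + 20.0) / 8.0), p.tauxr);
      put(Axs, Bxs, sig((v - 2.0) / 12.0), p.tauxs);
      put(Aa, Ba, sig((v - 5.0) / 9.0), 1.5);
      put(Ari, Bri, sig(-(v + 32.0) / 6.0), 25.0);
      put(Ay, By, sig(-(v + 72.0) / 7.0), p.tauy);
      k1[i] = sig(-(v + 70.0) / 6.0);
      rkr[i] = sig(-(v + 15.0) / 22.0);
    }
  }
};

// Box-Muller standard normal with cached spare, deterministic per seed
struct Gauss {
  std::mt19937_64 eng;
  std::uniform_real_distribution<double> unif;
  bool has_spare = false;
  double spare = 0.0;
  explicit Gauss(uint64_t seed) : eng(seed), unif(0.0, 1.0) {}
  double operator()() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(eng), u2 = unif(eng);
    while (u1 <= 1e-300) u1 = unif(eng);
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 2.0 * M_PI * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
};

} // namespace

// [[Rcpp::export(name = ".simulate_ap_cpp")]]
List simulate_ap_cpp(NumericVector ionic,
                     double gkr_scale,
                     int drug_mode,          // 0 none/simple (via gkr_scale), 1 state-dependent
                     double drug_conc,       // ng/mL
                     double k_on,            // per ng/mL per ms
                     double k_off,           // per ms
                     bool spontaneous,
                     double stim_amp,        // uA/uF, depolarising (>0)
                     double stim_dur,        // ms
                     double cycle_length,    // ms (paced mode)
                     int conditioning_beats,
                     int noisy_beats,
                     double xi,              // noise diffusion coefficient
                     double dt,              // internal step, ms
                     double dt_out,          // output step, ms
                     double v0,              // initial voltage, mV
                     uint64_t seed,
                     double tail_ms = 710.0, // recorded after final upstroke/stimulus
                     double max_ms = 0.0) {
  if (dt <= 0 || dt > 0.01 + 1e-12)
    stop("internal integration step must be positive and <= 0.01 ms");
  if (dt_out <= 0) stop("dt_out must be positive");
  if (xi < 0) stop("noise amplitude xi must be >= 0");
  if (drug_mode == 1 && (drug_conc < 0 || k_on < 0 || k_off < 0))
    stop("state-dependent drug requires non-negative concentration and rates");
  Params p = unpack(ionic);
  if (p.cm <= 0) stop("membrane capacitance must be positive");

  const int total_beats = conditioning_beats + noisy_beats;
  if (noisy_beats < 1 && xi > 0) stop("noisy beats must be >= 1 when xi > 0");

  // simulation horizon
  double horizon;
  if (spontaneous) {
    double cl_guess = 1400.0; // generous upper bound on surrogate intrinsic CL
    horizon = (max_ms > 0) ? max_ms : (total_beats + 4) * cl_guess + tail_ms + 500.0;
  } else {
    horizon = (total_beats - 1) * cycle_length + tail_ms + 5.0;
    if (max_ms > 0) horizon = std::min(horizon, max_ms);
  }

  const int n_out = (int)std::floor(horizon / dt_out) + 1;
  std::vector<double> vout; vout.reserve(n_out);
  std::vector<double> iout; iout.reserve(n_out);
  std::vector<double> upstrokes; // ms, on the output grid

  State s = init_state(v0);
  Gauss rng(seed);
  const double sq_dt_noise = std::sqrt(dt_out); // stochastic increment grid = output grid
  const int sub = (int)std::round(dt_out / dt);
  if (std::fabs(sub * dt - dt_out) > 1e-9)
    stop("dt_out must be an integer multiple of dt");

  double t = 0.0;
  double last_up = -1e9;
  double prev_v_out = s.v;
  int beats_seen = 0;          // spontaneous upstrokes counted
  bool noise_on_flag = (conditioning_beats == 0);
  double noise_start = -1.0;   // ms; noise active for t >= noise_start
  double end_time = horizon;   // refined once the final beat is known
  bool end_known = false;

  if (!spontaneous) {
    noise_start = conditioning_beats * cycle_length;
    end_time = (total_beats - 1) * cycle_length + tail_ms;
    end_known = true;
  }

  vout.push_back(s.v);
  iout.push_back(0.0);

  long step = 0;
  Tables tb(dt, p);
  const double inv_h = 1.0 / Tables::h;
  while (t < end_time - 1e-9) {
    const double v = s.v;
    // table index + interpolation fraction
    double pos = (v - Tables::vlo) * inv_h;
    if (pos < 0) pos = 0;
    if (pos > Tables::n - 1.001) pos = Tables::n - 1.001;
    const int ix = (int)pos;
    const double fr = pos - ix;
    auto lk = [&](const std::vector<double>& T) {
      return T[ix] + fr * (T[ix + 1] - T[ix]);
    };
    const double rkr = lk(tb.rkr);
    const double k1inf = lk(tb.k1);

    // currents (uA/uF)
    const double ina  = p.gna * s.m * s.m * s.m * s.h * (v - p.ena);
    const double ical = p.gcal * s.d * s.f * (v - p.eca);
    double gkr_mult = gkr_scale;
    if (drug_mode == 1) gkr_mult *= (1.0 - s.b);
    const double ikr  = p.gkr * gkr_mult * s.xr * rkr * (v - p.ek);
    const double iks  = p.gks * s.xs * (v - p.ek);
    const double ito  = p.gto * s.a * s.ri * (v - p.ek);
    const double ik1  = p.gk1 * k1inf * (v - p.ek);
    const double iff  = p.gf * s.y * (v - p.ef);
    const double ibna = p.gbna * (v - p.ena);
    double itot = ina + ical + ikr + iks + ito + ik1 + iff + ibna;

    // stimulus (paced mode): depolarising current for stim_dur at each cycle
    double istim = 0.0;
    if (!spontaneous) {
      long beat_idx = (long)std::floor(t / cycle_length);
      double tbt = t - beat_idx * cycle_length;
      if (beat_idx < total_beats && tbt < stim_dur) istim = stim_amp;
    }

    // Forward Euler voltage update; the stochastic increment is applied on
    // the (coarser) noise grid below
    double vnext = v - itot * dt / p.cm + istim * dt;

    // gate updates (Forward Euler, tabulated coefficients)
    s.m  = lk(tb.Am) * s.m  + lk(tb.Bm);
    s.h  = lk(tb.Ah) * s.h  + lk(tb.Bh);
    s.d  = lk(tb.Ad) * s.d  + lk(tb.Bd);
    s.f  = lk(tb.Af) * s.f  + lk(tb.Bf);
    s.xr = lk(tb.Axr) * s.xr + lk(tb.Bxr);
    s.xs = lk(tb.Axs) * s.xs + lk(tb.Bxs);
    s.a  = lk(tb.Aa) * s.a  + lk(tb.Ba);
    s.ri = lk(tb.Ari) * s.ri + lk(tb.Bri);
    s.y  = lk(tb.Ay) * s.y  + lk(tb.By);
    if (drug_mode == 1) {
      const double popen = s.xr * rkr;
      s.b += dt * (k_on * drug_conc * popen * (1.0 - s.b) - k_off * s.b);
      if (s.b < 0) s.b = 0; if (s.b > 1) s.b = 1;
    }
    s.v = vnext;
    t += dt;
    ++step;

    if (!std::isfinite(s.v) || std::fabs(s.v) > 200.0)
      stop("numerical blow-up (|V| > 200 mV or non-finite) at t = %.1f ms (beat %d)",
           t, (int)(spontaneous ? beats_seen :
                    (long)std::floor(t / cycle_length)));

    // record on the output grid; detect upstrokes there (dV/dt > 10 mV/ms)
    if (step % sub == 0) {
      const bool noise_now = (xi > 0) &&
        (spontaneous ? noise_on_flag : (t >= noise_start));
      if (noise_now) s.v += xi * rng() * sq_dt_noise;
      vout.push_back(s.v);
      iout.push_back(itot);
      const double dvdt = (s.v - prev_v_out) / dt_out;
      if (dvdt > 10.0 && (t - last_up) > 250.0) {
        last_up = t;
        upstrokes.push_back(t - dt_out); // sample before the threshold crossing
        if (spontaneous) {
          ++beats_seen;
          if (beats_seen == conditioning_beats) noise_on_flag = true;
          if (beats_seen == total_beats && !end_known) {
            end_time = std::min(horizon, t + tail_ms);
            end_known = true;
          }
        }
      }
      prev_v_out = s.v;
    }
  }

  if (spontaneous && beats_seen < total_beats)
    stop("phenotype failed to beat spontaneously: %d of %d required upstrokes "
         "within %.0f ms", beats_seen, total_beats, horizon);

  return List::create(
    _["voltage"] = NumericVector(vout.begin(), vout.end()),
    _["current"] = NumericVector(iout.begin(), iout.end()),
    _["dt_out"] = dt_out,
    _["upstroke_times"] = NumericVector(upstrokes.begin(), upstrokes.end()),
    _["bound_fraction"] = s.b,
    _["end_time"] = t);
}
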