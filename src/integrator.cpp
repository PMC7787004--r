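// Fixed-step midpoint (second-order Runge-Kutta) integrator for networks of
// single-compartment Hodgkin-Huxley neurons with optional persistent sodium
// current, gap-junction coupling and first-order excitatory chemical synapses.
//
// Units: mV, ms, nS, pF, pA (nS * mV = pA; pA / pF = mV / ms).
//
// Gating nonlinearities are evaluated through piecewise-linear lookup tables
// on a 0.01 mV grid over [-120, 60] mV (interpolation error ~1e-7), the
// standard trick in HH network simulators; the R level exposes the exact
// closed forms for verification.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

const double V_MIN = -120.0;
const double V_MAX = 60.0;
const double V_STEP = 0.01;
const int N_TAB = static_cast<int>((V_MAX - V_MIN) / V_STEP) + 1; // 18001

// Boltzmann steady state: 1 / (1 + exp(sgn * (v - vhalf) / k)); sgn = -1 for
// activation (increasing in v), +1 for inactivation.
inline double boltz(double v, double vhalf, double k, double sgn) {
  return 1.0 / (1.0 + std::exp(sgn * (v - vhalf) / k));
}

// Bell-shaped time-constant profile: tau_max / cosh((v - vhalf) / k).
inline double tau_bell(double v, double tau_max, double vhalf, double k) {
  return tau_max / std::cosh((v - vhalf) / k);
}

struct GateTables {
  std::vector<double> m_na_inf, h_na_inf, tau_h_na;
  std::vector<double> m_nap_inf, h_nap_inf, sech_h_nap; // tau_h_nap = Thmax * sech
  std::vector<double> m_k_inf, tau_m_k, s_inf;

  GateTables() {
    m_na_inf.resize(N_TAB); h_na_inf.resize(N_TAB); tau_h_na.resize(N_TAB);
    m_nap_inf.resize(N_TAB); h_nap_inf.resize(N_TAB); sech_h_nap.resize(N_TAB);
    m_k_inf.resize(N_TAB); tau_m_k.resize(N_TAB); s_inf.resize(N_TAB);
    for (int i = 0; i < N_TAB; ++i) {
      double v = V_MIN + i * V_STEP;
      m_na_inf[i]  = boltz(v, -42.5, 6.5, -1.0);
      h_na_inf[i]  = boltz(v, -65.5, 10.2, 1.0);
      tau_h_na[i]  = tau_bell(v, 35.2, -65.5, 12.8);
      m_nap_inf[i] = boltz(v, -52.0, 3.2, -1.0);
      h_nap_inf[i] = boltz(v, -57.0, 5.0, 1.0);
      sech_h_nap[i] = 1.0 / std::cosh((v + 57.0) / 8.0);
      m_k_inf[i]   = boltz(v, -34.5, 5.0, -1.0);
      tau_m_k[i]   = tau_bell(v, 10.0, -34.5, 10.0);
      s_inf[i]     = boltz(v, -20.0, 2.0, -1.0);
    }
  }
};

const GateTables TAB; // built once per process

struct Lookup {
  int i;
  double f;
  explicit Lookup(double v) {
    double x = (v - V_MIN) / V_STEP;
    if (x < 0.0) x = 0.0;
    if (x > N_TAB - 1.001) x = N_TAB - 1.001;
    i = static_cast<int>(x);
    f = x - i;
  }
  inline double at(const std::vector<double>& t) const {
    return t[i] + (t[i + 1] - t[i]) * f;
  }
};

struct Net {
  int n;
  // per-neuron parameters
  std::vector<double> C, g_na, g_k, g_l, g_nap, e_na, e_k, e_l, t_hmax;
  std::vector<int> has_nap;
  // gap edges (undirected, stored once)
  std::vector<int> ga, gb;
  std::vector<double> gw;
  // chemical edges i -> j
  std::vector<int> si, sj;
  std::vector<double> sw;
  double g_syn, e_syn, alpha_s, tau_s;
};

inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// State layout: for neuron k, y[5*k + {0..4}] = V, h_na, h_nap, m_k, s.
// Gate values are clamped to [0,1] on read (the midpoint stage is not
// clamped) and time constants floored at dt: far into saturation the
// voltage-dependent time constants fall to microseconds, which would make
// the explicit scheme unstable while the gate is pinned at its steady state
// anyway.
void deriv(const Net& net, const std::vector<double>& y, std::vector<double>& dy,
           std::vector<double>& syn_in, std::vector<double>& gap_drive,
           double dt) {
  int n = net.n;
  std::fill(syn_in.begin(), syn_in.end(), 0.0);
  std::fill(gap_drive.begin(), gap_drive.end(), 0.0);
  for (size_t e = 0; e < net.si.size(); ++e)
    syn_in[net.sj[e]] += net.sw[e] * y[5 * net.si[e] + 4];
  for (size_t e = 0; e < net.ga.size(); ++e) {
    double d = net.gw[e] * (y[5 * net.gb[e]] - y[5 * net.ga[e]]); // g*(Vb - Va)
    gap_drive[net.ga[e]] += d;
    gap_drive[net.gb[e]] -= d;
  }
  for (int k = 0; k < n; ++k) {
    const double v = y[5 * k], h_na = clamp01(y[5 * k + 1]),
                 h_nap = clamp01(y[5 * k + 2]), m_k = clamp01(y[5 * k + 3]),
                 s = clamp01(y[5 * k + 4]);
    Lookup lk(v);
    double m_na = lk.at(TAB.m_na_inf);
    double i_na = net.g_na[k] * m_na * m_na * m_na * h_na * (v - net.e_na[k]);
    double i_k = net.g_k[k] * m_k * m_k * m_k * m_k * (v - net.e_k[k]);
    double i_l = net.g_l[k] * (v - net.e_l[k]);
    double i_nap = 0.0;
    if (net.has_nap[k])
      i_nap = net.g_nap[k] * lk.at(TAB.m_nap_inf) * h_nap * (v - net.e_na[k]);
    double i_syn = net.g_syn * syn_in[k] * (v - net.e_syn);
    // gap drive enters with depolarizing sign: +sum g_ij (V_i - V_j)
    dy[5 * k] = (-(i_na + i_nap + i_k + i_l + i_syn) + gap_drive[k]) / net.C[k];
    dy[5 * k + 1] = (lk.at(TAB.h_na_inf) - h_na) /
        std::max(lk.at(TAB.tau_h_na), dt);
    dy[5 * k + 2] = net.has_nap[k]
        ? (lk.at(TAB.h_nap_inf) - h_nap) /
            std::max(net.t_hmax[k] * lk.at(TAB.sech_h_nap), dt)
        : 0.0;
    dy[5 * k + 3] = (lk.at(TAB.m_k_inf) - m_k) /
        std::max(lk.at(TAB.tau_m_k), dt);
    dy[5 * k + 4] = net.alpha_s * lk.at(TAB.s_inf) * (1.0 - s) - s / net.tau_s;
  }
}

} // namespace

// [[Rcpp::export(name = ".integrate_cpp")]]
List integrate_cpp(List params, NumericMatrix state0,
                   IntegerVector gap_a, IntegerVector gap_b, NumericVector gap_w,
                   IntegerVector syn_i, IntegerVector syn_j, NumericVector syn_w,
                   double g_syn, double e_syn, double alpha_s, double tau_s,
                   double dt, double duration,
                   double spike_threshold, double refractory,
                   bool record_v, double record_dt) {
  Net net;
  net.n = state0.nrow();
  NumericVector C = params["c"], g_na = params["g_na"], g_k = params["g_k"],
                g_l = params["g_l"], g_nap = params["g_nap"], e_na = params["e_na"],
                e_k = params["e_k"], e_l = params["e_l"], t_hmax = params["t_hmax"];
  IntegerVector has_nap = params["has_nap"];
  int n = net.n;
  net.C.assign(C.begin(), C.end());
  net.g_na.assign(g_na.begin(), g_na.end());
  net.g_k.assign(g_k.begin(), g_k.end());
  net.g_l.assign(g_l.begin(), g_l.end());
  net.g_nap.assign(g_nap.begin(), g_nap.end());
  net.e_na.assign(e_na.begin(), e_na.end());
  net.e_k.assign(e_k.begin(), e_k.end());
  net.e_l.assign(e_l.begin(), e_l.end());
  net.t_hmax.assign(t_hmax.begin(), t_hmax.end());
  net.has_nap.assign(has_nap.begin(), has_nap.end());
  net.ga.assign(gap_a.begin(), gap_a.end());
  net.gb.assign(gap_b.begin(), gap_b.end());
  net.gw.assign(gap_w.begin(), gap_w.end());
  net.si.assign(syn_i.begin(), syn_i.end());
  net.sj.assign(syn_j.begin(), syn_j.end());
  net.sw.assign(syn_w.begin(), syn_w.end());
  net.g_syn = g_syn; net.e_syn = e_syn;
  net.alpha_s = alpha_s; net.tau_s = tau_s;

  long n_steps = static_cast<long>(std::llround(duration / dt));
  long rec_every = record_v ? std::max(1L, static_cast<long>(std::llround(record_dt / dt))) : 0;
  long n_rec = record_v ? n_steps / rec_every + 1 : 0;

  std::vector<double> y(5 * n), k1(5 * n), k2(5 * n), ymid(5 * n);
  std::vector<double> syn_in(n), gap_drive(n);
  for (int k = 0; k < n; ++k)
    for (int c = 0; c < 5; ++c) y[5 * k + c] = state0(k, c);

  std::vector<std::vector<double> > spikes(n);
  std::vector<double> last_spike(n, -1e18);

  NumericMatrix vrec;
  NumericVector trec;
  if (record_v) {
    vrec = NumericMatrix(static_cast<int>(n_rec), n);
    trec = NumericVector(static_cast<int>(n_rec));
  }
  long irec = 0;
  if (record_v) {
    for (int k = 0; k < n; ++k) vrec(0, k) = y[5 * k];
    trec[0] = 0.0;
    irec = 1;
  }

  for (long step = 0; step < n_steps; ++step) {
    double t_new = (step + 1) * dt;
    deriv(net, y, k1, syn_in, gap_drive, dt);
    for (int q = 0; q < 5 * n; ++q) ymid[q] = y[q] + 0.5 * dt * k1[q];
    deriv(net, ymid, k2, syn_in, gap_drive, dt);
    for (int k = 0; k < n; ++k) {
      double v_old = y[5 * k];
      double v_new = v_old + dt * k2[5 * k];
      if (!std::isfinite(v_new))
        stop("non-finite membrane potential in neuron %d at t = %.3f ms",
             k + 1, t_new);
      y[5 * k] = v_new;
      for (int c = 1; c < 5; ++c)
        y[5 * k + c] = clamp01(y[5 * k + c] + dt * k2[5 * k + c]);
      if (v_old < spike_threshold && v_new >= spike_threshold &&
          t_new - last_spike[k] >= refractory) {
        spikes[k].push_back(t_new);
        last_spike[k] = t_new;
      }
    }
    if (record_v && (step + 1) % rec_every == 0 && irec < n_rec) {
      for (int k = 0; k < n; ++k) vrec(static_cast<int>(irec), k) = y[5 * k];
      trec[static_cast<int>(irec)] = t_new;
      ++irec;
    }
  }

  List spk(n);
  for (int k = 0; k < n; ++k) spk[k] = NumericVector(spikes[k].begin(), spikes[k].end());
  NumericMatrix yfin(n, 5);
  for (int k = 0; k < n; ++k)
    for (int c = 0; c < 5; ++c) yfin(k, c) = y[5 * k + c];

  List out = List::create(_["spikes"] = spk, _["final_state"] = yfin);
  if (record_v) {
    out["time"] = trec;
    out["v"] = vrec;
  }
  return out;
}
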