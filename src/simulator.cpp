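// Hodgkin-Huxley network integrator.
//
// 100 (or fewer) single-compartment HH neurons with Traub-Miles style
// kinetics parameterized by a threshold-shift potential V_T, slow AHP,
// conductance-based AMPA/NMDA synapses with Jahr-Stevens magnesium block,
// Tsodyks-Markram short-term depression, Wang-style asynchronous release,
// Ornstein-Uhlenbeck membrane noise, and distance-dependent conduction
// delays handled through a delivery ring buffer.
//
// Units: mV, ms, nS, pA, pF.  Conductance densities (mS/cm^2) are turned
// into absolute nS via the membrane area before entering here.
//
// Reproducibility: a self-contained xoshiro256++ generator with separate
// streams for initial conditions, membrane noise and asynchronous events,
// all derived from the single user seed via splitmix64.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

namespace {

struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  double norm() {  // Box-Muller
    if (have_spare) { have_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    double a = 6.283185307179586476925286766559 * v;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// y / (exp(y/s) - 1), continuous at y = 0
inline double vtrap(double y, double s) {
  if (std::fabs(y) < 1e-7) return s * (1.0 - y / (2.0 * s));
  return y / std::expm1(y / s);
}

// Traub-Miles rate functions (ms^-1), x = V - V_T (mV)
inline double alpha_m(double x) { return 0.32 * vtrap(13.0 - x, 4.0); }
inline double beta_m(double x)  { return 0.28 * vtrap(x - 40.0, 5.0); }
inline double alpha_h(double x) { return 0.128 * std::exp((17.0 - x) / 18.0); }
inline double beta_h(double x)  { return 4.0 / (1.0 + std::exp((40.0 - x) / 5.0)); }
inline double alpha_n(double x) { return 0.032 * vtrap(15.0 - x, 4.0); }
inline double beta_n(double x)  { return 0.5 * std::exp((10.0 - x) / 40.0); }

struct GateTable {
  // per-voltage-grid steady states and exponential-Euler decay factors
  double v0, inv_dv;
  int n;
  std::vector<double> minf, mdec, hinf, hdec, ninf, ndec;
  GateTable(double VT, double dt) {
    v0 = -150.0; inv_dv = 50.0;           // 0.02 mV grid
    n = static_cast<int>((100.0 - v0) * inv_dv) + 2;
    minf.resize(n); mdec.resize(n); hinf.resize(n);
    hdec.resize(n); ninf.resize(n); ndec.resize(n);
    for (int i = 0; i < n; ++i) {
      double v = v0 + i / inv_dv;
      double x = v - VT;
      double am = alpha_m(x), bm = beta_m(x);
      double ah = alpha_h(x), bh = beta_h(x);
      double an = alpha_n(x), bn = beta_n(x);
      minf[i] = am / (am + bm); mdec[i] = std::exp(-dt * (am + bm));
      hinf[i] = ah / (ah + bh); hdec[i] = std::exp(-dt * (ah + bh));
      ninf[i] = an / (an + bn); ndec[i] = std::exp(-dt * (an + bn));
    }
  }
  inline int idx(double v) const {
    int i = static_cast<int>((v - v0) * inv_dv);
    if (i < 0) i = 0;
    if (i >= n) i = n - 1;
    return i;
  }
};

}  // namespace

// [[Rcpp::export(name = ".simulate_network_cpp")]]
Rcpp::List simulate_network_cpp(
    int n_neurons,
    Rcpp::IntegerVector edge_from, Rcpp::IntegerVector edge_to,
    Rcpp::NumericVector edge_weight, Rcpp::NumericVector edge_delay_ms,
    Rcpp::NumericVector input_current,
    Rcpp::List free_params, Rcpp::List fixed, double duration_s,
    double seed) {
  const double dt = Rcpp::as<double>(fixed["dt"]);             // ms
  const double T_ms = duration_s * 1000.0;
  const long n_steps = static_cast<long>(std::ceil(T_ms / dt));

  // free parameters
  const double noise_sd = Rcpp::as<double>(free_params["noise_sd"]);
  const double gK_dens  = Rcpp::as<double>(free_params["g_K"]);
  const double gNa_dens = Rcpp::as<double>(free_params["g_Na"]);
  const double gAHP     = Rcpp::as<double>(free_params["g_AHP"]);
  const double gAMPA    = Rcpp::as<double>(free_params["g_AMPA"]);
  const double gNMDA    = Rcpp::as<double>(free_params["g_NMDA"]);
  const double tau_D    = Rcpp::as<double>(free_params["tau_D"]);
  const double U_std    = Rcpp::as<double>(free_params["U_std"]);
  const double U_asyn   = Rcpp::as<double>(free_params["U_asyn"]);

  // fixed parameters
  const double area   = Rcpp::as<double>(fixed["area"]);       // um^2
  const double C      = Rcpp::as<double>(fixed["C_m"]) * area * 1e-2;  // pF
  const double dens2nS = area * 1e-2;  // mS/cm^2 -> nS for this area
  const double gl   = Rcpp::as<double>(fixed["g_l"]) * dens2nS;
  const double gNa  = gNa_dens * dens2nS;
  const double gK   = gK_dens * dens2nS;
  const double E_K  = Rcpp::as<double>(fixed["E_K"]);
  const double E_Na = Rcpp::as<double>(fixed["E_Na"]);
  const double E_l  = Rcpp::as<double>(fixed["E_l"]);
  const double V_T  = Rcpp::as<double>(fixed["V_T"]);
  const double alpha_Ca = Rcpp::as<double>(fixed["alpha_Ca"]);
  const double tau_AHP_ms = Rcpp::as<double>(fixed["tau_AHP"]) * 1000.0;
  const double E_AMPA = Rcpp::as<double>(fixed["E_AMPA"]);
  const double E_NMDA = Rcpp::as<double>(fixed["E_NMDA"]);
  const double alpha_NMDA = Rcpp::as<double>(fixed["alpha_NMDA"]); // 1/ms
  const double tau_AMPA = Rcpp::as<double>(fixed["tau_AMPA"]);
  const double tau_Nd = Rcpp::as<double>(fixed["tau_NMDA_decay"]);
  const double tau_Nr = Rcpp::as<double>(fixed["tau_NMDA_rise"]);
  const double tau_asyn = Rcpp::as<double>(fixed["tau_asyn"]);
  const double U_max = Rcpp::as<double>(fixed["U_max"]);
  const double x_0 = Rcpp::as<double>(fixed["x_0"]);
  const double tau_noise = Rcpp::as<double>(fixed["tau_noise"]);
  const double mg = Rcpp::as<double>(fixed["mg_conc"]);
  const double refractory = Rcpp::as<double>(fixed["refractory"]);

  // precomputed decay factors
  const double dec_AHP  = std::exp(-dt / tau_AHP_ms);
  const double dec_AMPA = std::exp(-dt / tau_AMPA);
  const double dec_Nd   = std::exp(-dt / tau_Nd);
  const double dec_Nr   = std::exp(-dt / tau_Nr);
  const double dec_asyn = std::exp(-dt / tau_asyn);
  const double dec_ou   = std::exp(-dt / tau_noise);
  const double sig_ou   = noise_sd * std::sqrt(1.0 - dec_ou * dec_ou);

  GateTable tab(V_T, dt);

  // adjacency: CSR by presynaptic neuron
  const int n_edges = edge_from.size();
  std::vector<int> deg(n_neurons, 0);
  for (int e = 0; e < n_edges; ++e) deg[edge_from[e]]++;
  std::vector<int> off(n_neurons + 1, 0);
  for (int i = 0; i < n_neurons; ++i) off[i + 1] = off[i] + deg[i];
  std::vector<int> tgt(n_edges), dly(n_edges);
  std::vector<double> wgt(n_edges);
  {
    std::vector<int> cur(off.begin(), off.end() - 1);
    for (int e = 0; e < n_edges; ++e) {
      int i = edge_from[e];
      int p = cur[i]++;
      tgt[p] = edge_to[e];
      wgt[p] = edge_weight[e];
      int ds = static_cast<int>(std::lround(edge_delay_ms[e] / dt));
      dly[p] = ds < 1 ? 1 : ds;
    }
  }
  int max_dsteps = 1;
  for (int e = 0; e < n_edges; ++e) if (dly[e] > max_dsteps) max_dsteps = dly[e];
  const int ring_len = max_dsteps + 1;
  std::vector<double> ring(static_cast<size_t>(ring_len) * n_neurons, 0.0);

  // RNG streams
  uint64_t base = static_cast<uint64_t>(seed);
  Xoshiro rng_init(Xoshiro::splitmix64(base) ^ 0x1111111111111111ULL);
  Xoshiro rng_noise(Xoshiro::splitmix64(base) ^ 0x2222222222222222ULL);
  Xoshiro rng_asyn(Xoshiro::splitmix64(base) ^ 0x3333333333333333ULL);

  // state
  std::vector<double> V(n_neurons), m(n_neurons), h(n_neurons), nn(n_neurons),
      cahp(n_neurons, 0.0), eta(n_neurons), sA(n_neurons, 0.0),
      xr(n_neurons, 0.0), sN(n_neurons, 0.0), xres(n_neurons, 1.0),
      ares(n_neurons, 0.0), last_spike(n_neurons, -1e9);
  for (int i = 0; i < n_neurons; ++i) {
    V[i] = E_l + 2.0 * rng_init.norm();
    int ix = tab.idx(V[i]);
    m[i] = tab.minf[ix]; h[i] = tab.hinf[ix]; nn[i] = tab.ninf[ix];
    eta[i] = noise_sd * rng_init.norm();
  }

  std::vector<int> sp_neuron;
  std::vector<double> sp_time;
  sp_neuron.reserve(100000);
  sp_time.reserve(100000);

  const bool any_asyn = (U_asyn > 0.0) && (n_edges > 0);

  for (long t = 0; t < n_steps; ++t) {
    const double t_ms = t * dt;
    double *slot = &ring[static_cast<size_t>(t % ring_len) * n_neurons];
    for (int i = 0; i < n_neurons; ++i) {
      // synaptic deliveries scheduled for this step
      double amt = slot[i];
      if (amt != 0.0) { sA[i] += amt; xr[i] += amt; slot[i] = 0.0; }

      double v = V[i];
      int ix = tab.idx(v);
      m[i] = tab.minf[ix] + (m[i] - tab.minf[ix]) * tab.mdec[ix];
      h[i] = tab.hinf[ix] + (h[i] - tab.hinf[ix]) * tab.hdec[ix];
      nn[i] = tab.ninf[ix] + (nn[i] - tab.ninf[ix]) * tab.ndec[ix];
      cahp[i] *= dec_AHP;
      sA[i] *= dec_AMPA;
      sN[i] = sN[i] * dec_Nd + alpha_NMDA * xr[i] * dt;
      xr[i] *= dec_Nr;
      if (any_asyn) ares[i] *= dec_asyn;

      const double B = 1.0 / (1.0 + mg / 3.57 * std::exp(-0.062 * v));
      const double m2 = m[i] * m[i];
      const double gna_i = gNa * m2 * m[i] * h[i];
      const double n2 = nn[i] * nn[i];
      const double gk_i = gK * n2 * n2;
      const double gahp_i = gAHP * cahp[i];
      const double gampa_i = gAMPA * sA[i];
      const double gnmda_i = gNMDA * sN[i] * B;
      const double gtot = gl + gna_i + gk_i + gahp_i + gampa_i + gnmda_i;
      const double veq = (gl * E_l + gna_i * E_Na + gk_i * E_K +
                          gahp_i * E_K + gampa_i * E_AMPA +
                          gnmda_i * E_NMDA + input_current[i]) / gtot;
      double vnew = veq + (v - veq) * std::exp(-dt * gtot / C);

      // OU membrane fluctuation, increment added to V
      if (noise_sd > 0.0) {
        double eta_new = eta[i] * dec_ou + sig_ou * rng_noise.norm();
        vnew += eta_new - eta[i];
        eta[i] = eta_new;
      }

      if (!std::isfinite(vnew) || std::fabs(vnew) > 200.0) {
        Rcpp::stop("simulation failure: |V| exceeded 200 mV at t = %.3f ms "
                   "(neuron %d); reduce dt or check parameters",
                   t_ms, i + 1);
      }

      // upward threshold crossing at 0 mV with refractory dead time
      if (v < 0.0 && vnew >= 0.0 && (t_ms - last_spike[i]) >= refractory) {
        last_spike[i] = t_ms;
        sp_neuron.push_back(i);
        sp_time.push_back(t_ms * 1e-3);
        cahp[i] += alpha_Ca;
        if (n_edges > 0 && off[i + 1] > off[i]) {
          const double rel = U_std * xres[i];        // evoked release
          xres[i] -= rel;
          const double amount = rel;
          for (int p = off[i]; p < off[i + 1]; ++p) {
            long at = (t + dly[p]) % ring_len;
            ring[static_cast<size_t>(at) * n_neurons + tgt[p]] +=
                wgt[p] * amount;
          }
        }
        if (any_asyn) {
          ares[i] += U_asyn;
          if (ares[i] > U_max) ares[i] = U_max;
        }
      }

      // asynchronous release: single-vesicle events at rate ares (1/ms)
      if (any_asyn && ares[i] > 0.0 && off[i + 1] > off[i]) {
        if (rng_asyn.unif() < ares[i] * dt) {
          // single-vesicle quantum: 1/x_0 of an evoked release
          const double rel = U_std * xres[i] / x_0;
          xres[i] -= rel;
          const double amount = rel;
          for (int p = off[i]; p < off[i + 1]; ++p) {
            long at = (t + dly[p]) % ring_len;
            ring[static_cast<size_t>(at) * n_neurons + tgt[p]] +=
                wgt[p] * amount;
          }
        }
      }

      // STD recovery
      xres[i] += (1.0 - xres[i]) * (dt / tau_D);
      V[i] = vnew;
    }
    if ((t & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("neuron") = Rcpp::wrap(sp_neuron),
      Rcpp::Named("time_s") = Rcpp::wrap(sp_time));
}
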