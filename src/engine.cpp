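// Euler-Maruyama integration of the STN-GPe circuit.
//
// Dynamical neurons are adaptive quadratic integrate-and-fire units; cortex
// (CTX) and striatum (MSN) are Poisson spike generators.  Synapses are
// conductance-based (AMPA / NMDA with magnesium block / GABA-A) with pooled
// per-target conductance states and delayed spike delivery through per-
// projection ring buffers.  All stochasticity (membrane noise, Poisson
// generators, stimulus recruitment, MSN response kernel) is drawn from one
// xoshiro256++ stream seeded by the caller, so runs are reproducible from a
// single integer seed.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ with Box-Muller normals (R's RNG API is too slow for the
// ~1e8 normal draws of a 40 s network run).

namespace {

struct Xoshiro {
  uint64_t s[4];
  // ziggurat tables for standard normals (Marsaglia & Tsang, 128 strips)
  double wn[128], fn[128];
  uint32_t kn[128];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
      x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
      s[i] = x ^ (x >> 31);
    }
    init_ziggurat();
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline uint32_t next32() { return (uint32_t)(next() >> 32); }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  void init_ziggurat() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  inline double norm() {
    for (;;) {
      int32_t hz = (int32_t)next32();
      uint32_t iz = (uint32_t)hz & 127u;
      uint32_t az = (hz < 0) ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (az < kn[iz]) return hz * wn[iz];
      const double r = 3.442619855899;
      if (iz == 0) {  // base-strip tail
        double x, y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -r - x;
      }
      double x = hz * wn[iz];
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
  // steps until next success of a per-step Bernoulli(p), >= 1
  inline int64_t geom_wait(double p) {
    if (p <= 0.0) return std::numeric_limits<int64_t>::max() / 4;
    if (p >= 1.0) return 1;
    return 1 + (int64_t)std::floor(std::log(unif()) / std::log1p(-p));
  }
};

struct AqifParams {
  double k, vr, vt, a, b, vpeak, c, d, Ibias;
  // STN-only slow-variable terms (unused for GPe: w = 0, at = 0)
  double w, vrt, at, bt, dt2;
  bool has_u2;
};

AqifParams paramsFromList(const List& p, bool has_u2) {
  AqifParams q;
  q.k = as<double>(p["k"]);     q.vr = as<double>(p["v_r"]);
  q.vt = as<double>(p["v_t"]);  q.a = as<double>(p["a"]);
  q.b = as<double>(p["b"]);     q.vpeak = as<double>(p["v_peak"]);
  q.c = as<double>(p["c"]);     q.d = as<double>(p["d"]);
  q.Ibias = as<double>(p["I_bias"]);
  q.has_u2 = has_u2;
  if (has_u2) {
    q.w = as<double>(p["w"]);        q.vrt = as<double>(p["v_r_tilde"]);
    q.at = as<double>(p["a_tilde"]); q.bt = as<double>(p["b_tilde"]);
    q.dt2 = as<double>(p["d_tilde"]);
  } else {
    q.w = 0.0; q.vrt = 0.0; q.at = 0.0; q.bt = 0.0; q.dt2 = 0.0;
  }
  return q;
}

inline double mg_block_exact(double v) {
  return 1.0 / (1.0 + 0.28 * std::exp(-0.062 * v));
}

// tabulated magnesium block with linear interpolation (0.1 mV grid,
// interpolation error < 1e-5); the exact form is used out of range
struct MgLut {
  static const int N = 3001;
  double lo, step, inv, tab[N];
  MgLut() : lo(-200.0), step(0.1), inv(10.0) {
    for (int i = 0; i < N; ++i) tab[i] = mg_block_exact(lo + i * step);
  }
  inline double operator()(double v) const {
    double x = (v - lo) * inv;
    if (x < 0.0 || x >= N - 1) return mg_block_exact(v);
    int i = (int)x;
    double f = x - i;
    return tab[i] + f * (tab[i + 1] - tab[i]);
  }
};
static const MgLut mg_block;

// One Euler-Maruyama step of an aQIF neuron; returns true if the neuron was
// reset (spiked).  Derivatives are evaluated at the pre-step state.
inline bool step_neuron(const AqifParams& P, double dtms, double C,
                        double I, double noise_incr,
                        double& v, double& u1, double& u2) {
  double dv = dtms * (P.k * (v - P.vr) * (v - P.vt) - u1 - P.w * u2 + I) / C
              + noise_incr;
  double du1 = dtms * P.a * (P.b * (v - P.vr) - u1);
  if (P.has_u2) {
    double gate = (v < P.vrt) ? P.bt * (v - P.vrt) : 0.0;
    u2 += dtms * P.at * (gate - u2);
  }
  v += dv;
  u1 += du1;
  if (P.has_u2) {
    double U = 1.0 / (P.w * std::fabs(u2) + 1.0 / P.w);
    if (v >= P.vpeak + U * u2) {
      v = P.c - U * u2;
      u1 += P.d;
      u2 += P.dt2;
      return true;
    }
  } else if (v >= P.vpeak) {
    v = P.c;
    u1 += P.d;
    return true;
  }
  return false;
}

// Projection: CSR edge list plus one ring buffer of pending arrivals.
struct Projection {
  bool active;
  int kind;            // 0 = glutamatergic (AMPA + NMDA), 1 = GABA
  double G_ampa, G_nmda, G_gaba;
  int delay_steps;
  std::vector<int> ptr, tgt;          // CSR over presynaptic ids
  std::vector<std::vector<int>> ring; // pending postsynaptic arrivals
  void init_ring() {
    ring.assign(delay_steps + 1, std::vector<int>());
  }
  inline void enqueue(int pre, int64_t step_now) {
    if (!active) return;
    size_t slot = (size_t)((step_now + delay_steps) % (int64_t)ring.size());
    for (int k = ptr[pre]; k < ptr[pre + 1]; ++k)
      ring[slot].push_back(tgt[k]);
  }
};

Projection projFromList(const List& pl) {
  Projection p;
  p.active = as<bool>(pl["active"]);
  p.kind = as<int>(pl["kind"]);
  p.G_ampa = as<double>(pl["G_ampa"]);
  p.G_nmda = as<double>(pl["G_nmda"]);
  p.G_gaba = as<double>(pl["G_gaba"]);
  p.delay_steps = as<int>(pl["delay_steps"]);
  IntegerVector ptr = pl["ptr"], tgt = pl["tgt"];
  p.ptr.assign(ptr.begin(), ptr.end());
  p.tgt.assign(tgt.begin(), tgt.end());
  if (p.G_ampa == 0.0 && p.G_nmda == 0.0 && p.G_gaba == 0.0) p.active = false;
  p.init_ring();
  return p;
}

struct SpikeSink {
  std::vector<int> id;
  std::vector<double> t;
  std::vector<int> pop;
  bool record;
  double record_from;
  void push(int pop_code, int neuron, double time) {
    if (record && time >= record_from) {
      pop.push_back(pop_code); id.push_back(neuron); t.push_back(time);
    }
  }
};

} // namespace

// ---------------------------------------------------------------------------
// Full-circuit simulation.
//
// `net` is assembled by the R wrapper (see run_simulation); it carries
// population descriptions, CSR projections with delays in steps, the stimulus
// schedule and the MSN response-kernel constants.

// [[Rcpp::export]]
List simulate_circuit_cpp(List net, double dtms, double duration,
                          double record_from, int seed) {
  Xoshiro rng((uint64_t)(uint32_t)seed * 2654435761ULL + 0x1234ABCDULL);

  const int64_t n_steps = (int64_t)std::llround(duration / dtms);

  // --- populations -------------------------------------------------------
  List ctx = net["ctx"], msn = net["msn"], stn = net["stn"], gpe = net["gpe"];

  const int n_ctx = as<int>(ctx["n"]);
  const int n_msn = as<int>(msn["n"]);
  const int n_stn = as<int>(stn["n"]);
  const int n_gpe = as<int>(gpe["n"]);

  const double r_ctx = as<double>(ctx["rate"]) / 1000.0; // 1/ms
  const double r_msn = as<double>(msn["rate"]) / 1000.0;

  const bool stn_dyn = as<std::string>(stn["mode"]) == "dynamical";
  const bool gpe_dyn = as<std::string>(gpe["mode"]) == "dynamical";
  const double stn_pois = stn_dyn ? 0.0 : as<double>(stn["rate"]) / 1000.0;
  const double gpe_pois = gpe_dyn ? 0.0 : as<double>(gpe["rate"]) / 1000.0;

  AqifParams Pstn = paramsFromList(stn["params"], true);
  AqifParams Pgpe = paramsFromList(gpe["params"], false);

  NumericVector stnC = stn["C"], stnV0 = stn["v0"];
  NumericVector gpeC = gpe["C"], gpeV0 = gpe["v0"];
  const double theta_stn = as<double>(stn["theta"]);
  const double theta_gpe = as<double>(gpe["theta"]);

  // noise convention: "membrane" adds sqrt(2*theta*dt)*N(0,1) to v;
  // "literal" uses the printed current term 2*theta*C*xi (=> 2*theta*sqrt(dt)
  // on v after division by C).
  const bool literal_noise = as<std::string>(net["noise"]) == "literal";
  const double sig_stn = literal_noise ? 2.0 * theta_stn * std::sqrt(dtms)
                                       : std::sqrt(2.0 * theta_stn * dtms);
  const double sig_gpe = literal_noise ? 2.0 * theta_gpe * std::sqrt(dtms)
                                       : std::sqrt(2.0 * theta_gpe * dtms);

  std::vector<double> v_stn(stnV0.begin(), stnV0.end());
  std::vector<double> u1_stn(n_stn, 0.0), u2_stn(n_stn, 0.0);
  std::vector<double> v_gpe(gpeV0.begin(), gpeV0.end());
  std::vector<double> u1_gpe(n_gpe, 0.0);
  {
    NumericVector u1s = stn["u10"], u2s = stn["u20"], u1g = gpe["u10"];
    for (int i = 0; i < n_stn; ++i) { u1_stn[i] = u1s[i]; u2_stn[i] = u2s[i]; }
    for (int i = 0; i < n_gpe; ++i) u1_gpe[i] = u1g[i];
  }

  // --- conductance states -------------------------------------------------
  // STN: CTX AMPA, CTX NMDA (slow/fast), GPe GABA
  std::vector<double> s_ga(n_stn, 0.0), s_gs(n_stn, 0.0), s_gf(n_stn, 0.0),
      s_gg(n_stn, 0.0);
  // GPe: STN AMPA, STN NMDA (slow/fast), MSN GABA, GPe GABA
  std::vector<double> g_ga(n_gpe, 0.0), g_gs(n_gpe, 0.0), g_gf(n_gpe, 0.0),
      g_gm(n_gpe, 0.0), g_gg(n_gpe, 0.0);

  List syn = net["synapse"];
  const double E_glu = as<double>(syn["E_glu"]);
  const double E_gaba_gpe_stn = as<double>(syn["E_gpe_stn"]);
  const double E_gaba_gpe = as<double>(syn["E_gaba_gpe"]);
  const double dec_ampa = 1.0 - dtms / as<double>(syn["tau_ampa"]);
  const double dec_nmda_s = 1.0 - dtms / as<double>(syn["tau_nmda_decay"]);
  const double dec_nmda_f = 1.0 - dtms / as<double>(syn["tau_nmda_rise"]);
  const double dec_gaba_stn = 1.0 - dtms / as<double>(syn["tau_gpe_stn"]);
  const double dec_gaba_gpe = 1.0 - dtms / as<double>(syn["tau_gaba_gpe"]);

  // --- projections --------------------------------------------------------
  List projs = net["projections"];
  Projection ctx_stn = projFromList(projs["ctx_stn"]);
  Projection gpe_stn = projFromList(projs["gpe_stn"]);
  Projection stn_gpe = projFromList(projs["stn_gpe"]);
  Projection msn_gpe = projFromList(projs["msn_gpe"]);
  Projection gpe_gpe = projFromList(projs["gpe_gpe"]);
  if (!stn_dyn) { ctx_stn.active = false; gpe_stn.active = false; }
  if (!gpe_dyn) { stn_gpe.active = false; msn_gpe.active = false;
                  gpe_gpe.active = false; }

  // --- Poisson generators (event heap over steps) -------------------------
  // encoded ids: [0,n_ctx) ctx, [n_ctx, n_ctx+n_msn) msn, then stn, gpe
  const int off_msn = n_ctx, off_stn = n_ctx + n_msn,
            off_gpe = n_ctx + n_msn + n_stn;
  typedef std::pair<int64_t, int> Ev;
  std::priority_queue<Ev, std::vector<Ev>, std::greater<Ev>> heap;
  const double p_ctx = r_ctx * dtms, p_msn = r_msn * dtms;
  const double p_stn = stn_pois * dtms, p_gpe = gpe_pois * dtms;
  for (int i = 0; i < n_ctx; ++i)
    if (p_ctx > 0) heap.push(Ev(rng.geom_wait(p_ctx) - 1, i));
  for (int i = 0; i < n_msn; ++i)
    if (p_msn > 0) heap.push(Ev(rng.geom_wait(p_msn) - 1, off_msn + i));
  if (!stn_dyn)
    for (int i = 0; i < n_stn; ++i)
      if (p_stn > 0) heap.push(Ev(rng.geom_wait(p_stn) - 1, off_stn + i));
  if (!gpe_dyn)
    for (int i = 0; i < n_gpe; ++i)
      if (p_gpe > 0) heap.push(Ev(rng.geom_wait(p_gpe) - 1, off_gpe + i));

  // --- stimulation --------------------------------------------------------
  NumericVector stim_time = net["stim_time"], stim_site = net["stim_site"];
  const double sigma_s = as<double>(net["sigma_s"]);
  NumericVector ctx_coord = ctx["coords"];
  IntegerVector ctx_to_msn = net["ctx_to_msn"]; // 0-based, may be empty
  int stim_ptr = 0;
  std::vector<int64_t> stim_step(stim_time.size());
  for (int i = 0; i < stim_time.size(); ++i)
    stim_step[i] = (int64_t)std::llround(stim_time[i] / dtms);

  // --- MSN response kernel -------------------------------------------------
  List kern = net["msn_kernel"];
  const double k_eta = as<double>(kern["eta"]);       // 1/ms
  const double k_mu = as<double>(kern["mu"]);
  const double k_sig = as<double>(kern["sigma"]);
  const double k_ts = as<double>(kern["t_start"]);
  const double k_te = as<double>(kern["t_end"]);
  const double k_del = as<double>(kern["delay"]);     // CTX->MSN latency
  const bool k_literal = as<bool>(kern["literal_ramp"]);
  std::vector<double> msn_t0(n_msn, -1e18);
  std::vector<char> msn_active(n_msn, 0);
  std::vector<int> active_msn;

  // --- recording -----------------------------------------------------------
  LogicalVector recpop = net["record"]; // ctx, msn, stn, gpe
  SpikeSink sink;
  sink.record = true;
  sink.record_from = record_from;
  const bool rec_ctx = recpop[0], rec_msn = recpop[1], rec_stn = recpop[2],
             rec_gpe = recpop[3];
  // optional per-neuron recording masks (1-based index vectors, or NULL)
  List rmask = net["record_mask"];
  std::vector<char> mask_stn(n_stn, 1), mask_gpe(n_gpe, 1);
  if (!Rf_isNull(rmask["stn"])) {
    std::fill(mask_stn.begin(), mask_stn.end(), 0);
    IntegerVector idx = rmask["stn"];
    for (int i = 0; i < idx.size(); ++i) mask_stn[idx[i] - 1] = 1;
  }
  if (!Rf_isNull(rmask["gpe"])) {
    std::fill(mask_gpe.begin(), mask_gpe.end(), 0);
    IntegerVector idx = rmask["gpe"];
    for (int i = 0; i < idx.size(); ++i) mask_gpe[idx[i] - 1] = 1;
  }

  auto emit_ctx = [&](int i, int64_t n, double t) {
    ctx_stn.enqueue(i, n);
    if (rec_ctx) sink.push(0, i, t);
  };
  auto emit_msn = [&](int i, int64_t n, double t) {
    msn_gpe.enqueue(i, n);
    if (rec_msn) sink.push(1, i, t);
  };
  auto emit_stn = [&](int i, int64_t n, double t) {
    stn_gpe.enqueue(i, n);
    if (rec_stn && mask_stn[i]) sink.push(2, i, t);
  };
  auto emit_gpe = [&](int i, int64_t n, double t) {
    gpe_stn.enqueue(i, n);
    gpe_gpe.enqueue(i, n);
    if (rec_gpe && mask_gpe[i]) sink.push(3, i, t);
  };

  // ---------------------------------------------------------------------
  for (int64_t n = 0; n < n_steps; ++n) {
    const double t = n * dtms;

    // deliver arrivals scheduled for this step
    if (ctx_stn.active) {
      std::vector<int>& slot = ctx_stn.ring[n % ctx_stn.ring.size()];
      for (int j : slot) {
        s_ga[j] += ctx_stn.G_ampa;
        s_gs[j] += ctx_stn.G_nmda; s_gf[j] += ctx_stn.G_nmda;
      }
      slot.clear();
    }
    if (gpe_stn.active) {
      std::vector<int>& slot = gpe_stn.ring[n % gpe_stn.ring.size()];
      for (int j : slot) s_gg[j] += gpe_stn.G_gaba;
      slot.clear();
    }
    if (stn_gpe.active) {
      std::vector<int>& slot = stn_gpe.ring[n % stn_gpe.ring.size()];
      for (int j : slot) {
        g_ga[j] += stn_gpe.G_ampa;
        g_gs[j] += stn_gpe.G_nmda; g_gf[j] += stn_gpe.G_nmda;
      }
      slot.clear();
    }
    if (msn_gpe.active) {
      std::vector<int>& slot = msn_gpe.ring[n % msn_gpe.ring.size()];
      for (int j : slot) g_gm[j] += msn_gpe.G_gaba;
      slot.clear();
    }
    if (gpe_gpe.active) {
      std::vector<int>& slot = gpe_gpe.ring[n % gpe_gpe.ring.size()];
      for (int j : slot) g_gg[j] += gpe_gpe.G_gaba;
      slot.clear();
    }

    // stimulus onsets: recruit CTX generators, arm MSN kernels
    while (stim_ptr < (int)stim_step.size() && stim_step[stim_ptr] == n) {
      const double s0 = stim_site[stim_ptr];
      for (int i = 0; i < n_ctx; ++i) {
        double z = (ctx_coord[i] - s0) / sigma_s;
        double P = 1.0 / (1.0 + z * z);
        if (rng.unif() < P) {
          emit_ctx(i, n, t);
          if (ctx_to_msn.size() == n_ctx) {
            int j = ctx_to_msn[i];
            msn_t0[j] = t;
            if (!msn_active[j]) { msn_active[j] = 1; active_msn.push_back(j); }
          }
        }
      }
      ++stim_ptr;
    }

    // baseline Poisson events
    while (!heap.empty() && heap.top().first == n) {
      int id = heap.top().second;
      heap.pop();
      if (id < off_msn) {
        emit_ctx(id, n, t);
        heap.push(Ev(n + rng.geom_wait(p_ctx), id));
      } else if (id < off_stn) {
        int j = id - off_msn;
        if (!msn_active[j]) { // kernel-armed MSNs are handled below
          emit_msn(j, n, t);
          heap.push(Ev(n + rng.geom_wait(p_msn), id));
        }
      } else if (id < off_gpe) {
        emit_stn(id - off_stn, n, t);
        heap.push(Ev(n + rng.geom_wait(p_stn), id));
      } else {
        emit_gpe(id - off_gpe, n, t);
        heap.push(Ev(n + rng.geom_wait(p_gpe), id));
      }
    }

    // kernel-armed MSNs: per-step Bernoulli with the evoked-rate profile
    for (size_t a = 0; a < active_msn.size();) {
      int j = active_msn[a];
      double tau = t - msn_t0[j] - k_del;
      double rate;
      bool done = false;
      if (tau <= 0.0) {
        rate = r_msn; // kernel not yet arrived; baseline rate
      } else if (tau < 2.0 * k_mu) {
        double z = (tau - k_mu) / k_sig;
        rate = k_eta * std::exp(-0.5 * z * z);
      } else if (tau < 2.0 * k_mu + k_ts) {
        rate = 0.0;   // silent period
      } else if (tau < 2.0 * k_mu + k_te) {
        rate = k_literal ? (tau - k_ts) / (k_te - k_ts)
                         : r_msn * (tau - 2.0 * k_mu - k_ts) / (k_te - k_ts);
      } else {
        done = true;  // recovered to baseline
        rate = r_msn;
      }
      if (!done) {
        if (rate > 0.0 && rng.unif() < rate * dtms) emit_msn(j, n, t);
        ++a;
      } else {
        msn_active[j] = 0;
        msn_t0[j] = -1e18;
        heap.push(Ev(n + rng.geom_wait(p_msn), off_msn + j));
        active_msn[a] = active_msn.back();
        active_msn.pop_back();
      }
    }

    // integrate dynamical neurons (state advances to t + dt)
    const double t_next = (n + 1) * dtms;
    if (stn_dyn) {
      for (int j = 0; j < n_stn; ++j) {
        double v = v_stn[j];
        double I = Pstn.Ibias
          + s_ga[j] * (E_glu - v)
          + mg_block(v) * (s_gs[j] - s_gf[j]) * (E_glu - v)
          + s_gg[j] * (E_gaba_gpe_stn - v);
        double nz = (sig_stn > 0.0) ? sig_stn * rng.norm() : 0.0;
        bool sp = step_neuron(Pstn, dtms, stnC[j], I, nz,
                              v_stn[j], u1_stn[j], u2_stn[j]);
        if (sp) emit_stn(j, n + 1, t_next);
      }
    }
    if (gpe_dyn) {
      for (int j = 0; j < n_gpe; ++j) {
        double v = v_gpe[j];
        double I = Pgpe.Ibias
          + g_ga[j] * (E_glu - v)
          + mg_block(v) * (g_gs[j] - g_gf[j]) * (E_glu - v)
          + g_gm[j] * (E_gaba_gpe - v)
          + g_gg[j] * (E_gaba_gpe - v);
        double dummy_u2 = 0.0;
        double nz = (sig_gpe > 0.0) ? sig_gpe * rng.norm() : 0.0;
        bool sp = step_neuron(Pgpe, dtms, gpeC[j], I, nz,
                              v_gpe[j], u1_gpe[j], dummy_u2);
        if (sp) emit_gpe(j, n + 1, t_next);
      }
    }

    // conductance decay (forward Euler of Eq tau dg/dt = -g)
    if (stn_dyn) {
      for (int j = 0; j < n_stn; ++j) {
        s_ga[j] *= dec_ampa;
        s_gs[j] *= dec_nmda_s; s_gf[j] *= dec_nmda_f;
        s_gg[j] *= dec_gaba_stn;
      }
    }
    if (gpe_dyn) {
      for (int j = 0; j < n_gpe; ++j) {
        g_ga[j] *= dec_ampa;
        g_gs[j] *= dec_nmda_s; g_gf[j] *= dec_nmda_f;
        g_gm[j] *= dec_gaba_gpe;
        g_gg[j] *= dec_gaba_gpe;
      }
    }

    if ((n & 0x3FF) == 0) {
      bool bad = false;
      if (stn_dyn && n_stn > 0 &&
          (!std::isfinite(v_stn[0]) || std::fabs(v_stn[0]) > 1e6))
        bad = true;
      if (gpe_dyn && n_gpe > 0 &&
          (!std::isfinite(v_gpe[0]) || std::fabs(v_gpe[0]) > 1e6))
        bad = true;
      if (bad)
        stop("numerical blow-up: divergent membrane potential at t=%f ms", t);
      Rcpp::checkUserInterrupt();
    }
  }
  for (int j = 0; stn_dyn && j < n_stn; ++j)
    if (!std::isfinite(v_stn[j]))
      stop("numerical blow-up: non-finite STN membrane potential (neuron %d)",
           j + 1);
  for (int j = 0; gpe_dyn && j < n_gpe; ++j)
    if (!std::isfinite(v_gpe[j]))
      stop("numerical blow-up: non-finite GPe membrane potential (neuron %d)",
           j + 1);

  return List::create(
      _["pop"] = IntegerVector(sink.pop.begin(), sink.pop.end()),
      _["neuron"] = IntegerVector(sink.id.begin(), sink.id.end()),
      _["time"] = NumericVector(sink.t.begin(), sink.t.end()));
}

// ---------------------------------------------------------------------------
// Single-neuron integrator sharing the network code path; used for
// deterministic trajectories, f-I curves and rebound protocols.

// [[Rcpp::export]]
List integrate_neuron_cpp(List params, bool is_stn, double C,
                          NumericVector I_applied, double dtms,
                          double v0, double u10, double u20,
                          double theta, int seed, bool record_v) {
  AqifParams P = paramsFromList(params, is_stn);
  const int64_t n_steps = I_applied.size();
  const double sig = std::sqrt(2.0 * theta * dtms);
  Xoshiro rng((uint64_t)(uint32_t)seed * 2654435761ULL + 0x5678EF01ULL);

  double v = v0, u1 = u10, u2 = u20;
  std::vector<double> vt;
  if (record_v) { vt.reserve(n_steps + 1); vt.push_back(v); }
  std::vector<double> spikes;

  for (int64_t n = 0; n < n_steps; ++n) {
    double noise = (theta > 0.0) ? sig * rng.norm() : 0.0;
    bool sp = step_neuron(P, dtms, C, I_applied[n] + P.Ibias, noise, v, u1, u2);
    if (sp) spikes.push_back((n + 1) * dtms);
    if (record_v) vt.push_back(v);
    if (!std::isfinite(v))
      stop("numerical blow-up: non-finite membrane potential at t=%f ms",
           (n + 1) * dtms);
  }
  return List::create(
      _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
      _["v"] = record_v ? NumericVector(vt.begin(), vt.end())
                        : NumericVector(0),
      _["state"] = NumericVector::create(v, u1, u2));
}
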