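// Clock-driven integration core for the dentate network model.
//
// All dynamic state lives in flat arrays; the R side assembles the network
// (compartments, channel instances, synapse slots, delayed edges) and passes
// it down as plain vectors.  Units: mV, ms, nA, uS, nF.  Voltage-dependent
// gating uses lookup tables (one entry per 0.05 mV) built in R from the
// kinetics definitions, so the kinetics remain swappable without recompiling.
//
// Integration: gating variables advance analytically
// (x <- xinf + (x - xinf) * exp(-dt/tau), table-precomputed decay) against
// the previous-step voltage; the voltage update is an implicit
// backward-Euler solve with Hines elimination over each compartment tree,
// with channel/synaptic conductances and reversal terms entering as
// Gtot/GE sums.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

const double V_TAB_MIN = -120.0;
const double V_TAB_MAX = 60.0;
const double V_TAB_STEP = 0.05;

inline int vidx(double v, int n) {
  int i = (int)((v - V_TAB_MIN) / V_TAB_STEP + 0.5);
  if (i < 0) i = 0;
  if (i >= n) i = n - 1;
  return i;
}

struct Gate {
  int power;
  std::vector<double> inf;   // xinf(V) table
  std::vector<double> dec;   // exp(-dt/tau(V)) table
  std::vector<double> state; // one per channel instance
};

// A channel "block": one mechanism on a set of compartments sharing tables.
struct Channel {
  std::string kind;          // "hh", "sk", "bk"
  std::vector<int> comp;     // compartment index per instance
  std::vector<double> gbar;  // uS per instance
  double erev;
  bool is_ca;                // contributes to Ca influx
  std::vector<Gate> gates;   // for kind == "hh"
  // sk params
  double sk_kd2, sk_dec;
  // bk params: K(V) table, fixed tau
  std::vector<double> bk_kv;
  double bk_dec;
  std::vector<double> state; // sk z / bk o per instance
};

} // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List net, List run) {
  // ---- compartments ----
  NumericVector C_nF = net["C_nF"];
  NumericVector g_leak = net["g_leak_uS"];
  NumericVector E_leak = net["E_leak_mV"];
  IntegerVector parent = net["parent"];       // 0-based, -1 root
  NumericVector g_ax = net["g_axial_uS"];     // to parent
  IntegerVector soma_comp = net["soma_comp"]; // per cell, 0-based
  NumericVector vthresh = net["spike_thresh"]; // per cell, mV
  const int ncomp = C_nF.size();
  const int ncell = soma_comp.size();

  // ---- calcium pools (optional per compartment) ----
  NumericVector ca_B = net["ca_B"];     // mol per nA*ms, 0 = no pool
  double ca_tau = as<double>(net["ca_tau_ms"]);
  double ca_ss = as<double>(net["ca_ss"]);
  double ca_dec = std::exp(-as<double>(run["dt"]) / ca_tau);

  // ---- channels ----
  List chl = net["channels"];
  std::vector<Channel> channels;
  for (int c = 0; c < chl.size(); ++c) {
    List ch = chl[c];
    Channel C;
    C.kind = as<std::string>(ch["kind"]);
    C.comp = as<std::vector<int>>(ch["comp"]);
    C.gbar = as<std::vector<double>>(ch["gbar"]);
    C.erev = as<double>(ch["erev"]);
    C.is_ca = as<bool>(ch["is_ca"]);
    if (C.kind == "hh") {
      List gl = ch["gates"];
      for (int g = 0; g < gl.size(); ++g) {
        List gg = gl[g];
        Gate G;
        G.power = as<int>(gg["power"]);
        G.inf = as<std::vector<double>>(gg["inf"]);
        G.dec = as<std::vector<double>>(gg["dec"]);
        G.state = as<std::vector<double>>(gg["state"]);
        C.gates.push_back(std::move(G));
      }
    } else if (C.kind == "sk") {
      double kd = as<double>(ch["kd"]);
      C.sk_kd2 = kd * kd;
      C.sk_dec = std::exp(-as<double>(run["dt"]) / as<double>(ch["tau"]));
      C.state = as<std::vector<double>>(ch["state"]);
    } else if (C.kind == "bk") {
      C.bk_kv = as<std::vector<double>>(ch["kv"]); // K(V) table (mol units)
      C.bk_dec = std::exp(-as<double>(run["dt"]) / as<double>(ch["tau"]));
      C.state = as<std::vector<double>>(ch["state"]);
    } else {
      stop("unknown channel kind");
    }
    channels.push_back(std::move(C));
  }
  int ntab = 0;
  for (auto &C : channels)
    for (auto &G : C.gates) ntab = std::max(ntab, (int)G.inf.size());
  if (ntab == 0) ntab = (int)((V_TAB_MAX - V_TAB_MIN) / V_TAB_STEP) + 1;

  // ---- synapse slots ----
  IntegerVector slot_comp = net["slot_comp"];   // 0-based compartment
  NumericVector slot_dr = net["slot_decay_r"];  // exp(-dt/tau_rise)
  NumericVector slot_df = net["slot_decay_f"];
  NumericVector slot_norm = net["slot_norm"];   // peak normalization
  NumericVector slot_erev = net["slot_erev"];
  const int nslot = slot_comp.size();

  // ---- edges (CSR over presynaptic sources) ----
  IntegerVector src_ptr = net["src_ptr"];       // length nsrc+1, 0-based
  IntegerVector edge_slot = net["edge_slot"];   // 0-based slot
  IntegerVector edge_delay = net["edge_delay"]; // steps
  IntegerVector edge_path = net["edge_path"];   // 0-based pathway id
  NumericVector path_w = run["pathway_weights"]; // uS (base * multiplier)
  const int nsrc = src_ptr.size() - 1;

  // ---- external (EC) source spikes ----
  IntegerVector ext_src = run["ext_src"];   // 0-based source index
  NumericVector ext_t = run["ext_t"];       // ms, sorted ascending

  // ---- run parameters ----
  const double dt = as<double>(run["dt"]);
  const double duration = as<double>(run["duration"]);
  const int nstep = (int)std::lround(duration / dt);
  const int refrac_steps = (int)std::lround(as<double>(run["refractory_ms"]) / dt);

  // current injections: (comp, amp nA, t0, t1)
  IntegerVector inj_comp = run["inj_comp"];
  NumericVector inj_amp = run["inj_amp"];
  NumericVector inj_t0 = run["inj_t0"];
  NumericVector inj_t1 = run["inj_t1"];

  // probes
  IntegerVector probe_comp = run["probe_comp"];
  int probe_every = as<int>(run["probe_every"]);
  int nprobe = probe_comp.size();
  int nrec = (nprobe > 0 && nstep > 0) ? ((nstep - 1) / probe_every + 1) : 0;
  NumericMatrix probes(nrec, nprobe);

  NumericVector V = clone(as<NumericVector>(net["V_init"]));
  std::vector<double> Ca(ncomp, ca_ss);
  std::vector<double> synA(nslot, 0.0), synB(nslot, 0.0);

  // ring buffer of pending synaptic weight arrivals
  int max_delay = 1;
  for (int e = 0; e < edge_delay.size(); ++e)
    if (edge_delay[e] + 1 > max_delay) max_delay = edge_delay[e] + 1;
  const int rb = max_delay + 1;
  std::vector<float> ring(std::max((size_t)1, (size_t)rb * nslot), 0.0f);

  std::vector<double> Gtot(ncomp), GE(ncomp), Ica(ncomp);
  std::vector<double> diag(ncomp), rhs(ncomp);
  std::vector<int> last_spike(ncell, -1000000);
  std::vector<double> Vprev(ncomp);

  std::vector<int> out_cell;
  std::vector<double> out_t;
  long long deliveries = 0;

  int ext_i = 0;
  const int next = ext_t.size();

  auto deliver = [&](int src, int step) {
    const int a = src_ptr[src], b = src_ptr[src + 1];
    for (int e = a; e < b; ++e) {
      int at = (step + edge_delay[e]) % rb;
      ring[(size_t)at * nslot + edge_slot[e]] += (float)path_w[edge_path[e]];
    }
    deliveries += (b - a);
  };

  int reci = 0;
  for (int step = 0; step < nstep; ++step) {
    const double t = step * dt;

    if (nprobe > 0 && step % probe_every == 0) {
      for (int p = 0; p < nprobe; ++p) probes(reci, p) = V[probe_comp[p]];
      ++reci;
    }

    // external spikes scheduled for this step
    while (ext_i < next && ext_t[ext_i] < t + dt) {
      deliver(ext_src[ext_i], step);
      ++ext_i;
    }

    // collect pending arrivals, advance synapse states
    if (nslot > 0) {
      float *row = &ring[(size_t)(step % rb) * nslot];
      for (int s = 0; s < nslot; ++s) {
        double w = row[s];
        row[s] = 0.0f;
        synA[s] = synA[s] * slot_dr[s] + w;
        synB[s] = synB[s] * slot_df[s] + w;
      }
    }

    std::fill(Gtot.begin(), Gtot.end(), 0.0);
    std::fill(GE.begin(), GE.end(), 0.0);
    std::fill(Ica.begin(), Ica.end(), 0.0);

    // synaptic conductances
    for (int s = 0; s < nslot; ++s) {
      double g = slot_norm[s] * (synB[s] - synA[s]);
      if (g > 0) {
        int c = slot_comp[s];
        Gtot[c] += g;
        GE[c] += g * slot_erev[s];
      }
    }

    // leak
    for (int c = 0; c < ncomp; ++c) {
      Gtot[c] += g_leak[c];
      GE[c] += g_leak[c] * E_leak[c];
    }

    // voltage/Ca-gated channels
    for (auto &C : channels) {
      const int n = (int)C.comp.size();
      if (C.kind == "hh") {
        for (int i = 0; i < n; ++i) {
          const int c = C.comp[i];
          const int iv = vidx(V[c], ntab);
          double open = 1.0;
          for (auto &G : C.gates) {
            double x = G.inf[iv] + (G.state[i] - G.inf[iv]) * G.dec[iv];
            G.state[i] = x;
            switch (G.power) {
              case 1: open *= x; break;
              case 2: open *= x * x; break;
              case 3: open *= x * x * x; break;
              case 4: { double x2 = x * x; open *= x2 * x2; } break;
              default: open *= std::pow(x, G.power);
            }
          }
          double g = C.gbar[i] * open;
          Gtot[c] += g;
          GE[c] += g * C.erev;
          if (C.is_ca) Ica[c] += g * (V[c] - C.erev); // nA, negative inward
        }
      } else if (C.kind == "sk") {
        for (int i = 0; i < n; ++i) {
          const int c = C.comp[i];
          double ca2 = Ca[c] * Ca[c];
          double zinf = ca2 / (ca2 + C.sk_kd2);
          double z = zinf + (C.state[i] - zinf) * C.sk_dec;
          C.state[i] = z;
          double g = C.gbar[i] * z;
          Gtot[c] += g;
          GE[c] += g * C.erev;
        }
      } else { // bk
        for (int i = 0; i < n; ++i) {
          const int c = C.comp[i];
          const int iv = vidx(V[c], (int)C.bk_kv.size());
          double oinf = Ca[c] / (Ca[c] + C.bk_kv[iv]);
          double o = oinf + (C.state[i] - oinf) * C.bk_dec;
          C.state[i] = o;
          double g = C.gbar[i] * o;
          Gtot[c] += g;
          GE[c] += g * C.erev;
        }
      }
    }

    // calcium pools: dCa/dt = -B*Ica - (Ca - ca_ss)/tau  (Ica<0 raises Ca)
    for (int c = 0; c < ncomp; ++c) {
      if (ca_B[c] > 0) {
        double target = ca_ss - ca_B[c] * Ica[c] * ca_tau;
        double ca = target + (Ca[c] - target) * ca_dec;
        Ca[c] = ca > 0 ? ca : 0.0;
      }
    }

    // injected currents
    for (int k = 0; k < inj_comp.size(); ++k) {
      if (t >= inj_t0[k] && t < inj_t1[k]) GE[inj_comp[k]] += inj_amp[k];
    }

    // implicit (backward-Euler) voltage update with Hines elimination over
    // the compartment trees; parent[c] < c by construction
    std::copy(V.begin(), V.end(), Vprev.begin());
    for (int c = 0; c < ncomp; ++c) {
      diag[c] = C_nF[c] / dt + Gtot[c];
      rhs[c] = C_nF[c] / dt * V[c] + GE[c];
      int p = parent[c];
      if (p >= 0) {
        diag[c] += g_ax[c];
        diag[p] += g_ax[c];
      }
    }
    for (int c = ncomp - 1; c > 0; --c) {
      int p = parent[c];
      if (p >= 0) {
        double f = g_ax[c] / diag[c];
        diag[p] -= f * g_ax[c];
        rhs[p] += f * rhs[c];
      }
    }
    for (int c = 0; c < ncomp; ++c) {
      int p = parent[c];
      V[c] = (p >= 0) ? (rhs[c] + g_ax[c] * V[p]) / diag[c]
                      : rhs[c] / diag[c];
      if (!std::isfinite(V[c]) || V[c] < -200.0 || V[c] > 150.0)
        stop("numerical instability at compartment %d, t = %.2f ms (V = %f)",
             c + 1, t, V[c]);
    }

    // threshold crossings at somata
    for (int cell = 0; cell < ncell; ++cell) {
      const int sc = soma_comp[cell];
      if (Vprev[sc] < vthresh[cell] && V[sc] >= vthresh[cell] &&
          step - last_spike[cell] >= refrac_steps) {
        last_spike[cell] = step;
        out_cell.push_back(cell);
        out_t.push_back(t + 0.5 * dt);
        if (cell < nsrc) deliver(cell, step);
      }
    }
  }

  return List::create(
    _["spike_cell"] = wrap(out_cell), // 0-based internal cell index
    _["spike_t"] = wrap(out_t),
    _["deliveries"] = (double)deliveries,
    _["probes"] = probes,
    _["V_final"] = V);
}
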