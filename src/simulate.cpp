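// Forward-Euler integration of a conductance-based LIF ring network:
// pyramidal cells with Gaussian recurrent excitation (AMPA + saturating
// NMDA with Mg block), unstructured coupling with fast-spiking
// interneurons (GABA), and point-conductance background noise updated by
// the exact discrete Ornstein-Uhlenbeck step. Single-network and coupled
// two-network (timing -> decision) entry points share the same machinery.
//
// Units: nS, nF, mV, pA, ms. All randomness comes from R's RNG so
// set.seed() in R makes every simulation reproducible.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct PopPar {
  int n;
  double Cm, gL, VL, Vth, Vres, tref;
};

struct TargetSyn {            // receptor parameters by target population
  double gA, tauA, gN, tauN, gG, tauG;
};

struct NoisePar {
  double ge0, gi0, taue, taui, De, Di;
};

struct Pulse {
  int pop;                    // 0 = pyramidal, 1 = interneuron
  double t0, t1, factor;      // g_e0 <- factor * reference during [t0, t1)
};

PopPar as_pop(const List& p) {
  PopPar o;
  o.n = as<int>(p["n"]);
  o.Cm = as<double>(p["membrane_capacitance"]);
  o.gL = as<double>(p["leak_conductance"]);
  o.VL = as<double>(p["leak_reversal"]);
  o.Vth = as<double>(p["spike_threshold"]);
  o.Vres = as<double>(p["reset_potential"]);
  o.tref = as<double>(p["refractory_period"]);
  return o;
}

TargetSyn as_syn(const List& s) {
  TargetSyn o;
  o.gA = as<double>(s["g_ampa"]); o.tauA = as<double>(s["tau_ampa"]);
  o.gN = as<double>(s["g_nmda"]); o.tauN = as<double>(s["tau_nmda"]);
  o.gG = as<double>(s["g_gaba"]); o.tauG = as<double>(s["tau_gaba"]);
  return o;
}

NoisePar as_noise(const List& nz) {
  NoisePar o;
  o.ge0 = as<double>(nz["mean_exc_conductance"]);
  o.gi0 = as<double>(nz["mean_inh_conductance"]);
  o.taue = as<double>(nz["exc_time_constant"]);
  o.taui = as<double>(nz["inh_time_constant"]);
  o.De = as<double>(nz["exc_diffusion"]);
  o.Di = as<double>(nz["inh_diffusion"]);
  return o;
}

inline double mg_block(double v, double mg) {
  return 1.0 / (1.0 + mg * std::exp(-0.062 * v) / 3.57);
}

// One local circuit: parameters, state, and a step() that integrates dt.
struct Net {
  PopPar E, I;
  TargetSyn onE, onI;         // receptors at synapses onto E / onto I
  NoisePar nzE, nzI;
  double VE, VI, mg, alpha, taux, rho, ref_ge0;
  double dt;

  const double* W;            // nE x nE column-major pyramidal weights

  // state
  std::vector<double> vE, vI, refE, refI;
  std::vector<double> sA_E, sA_I, xE, xI, sN_E, sN_I;   // per E presyn
  std::vector<double> sG_E, sG_I;                       // per I presyn
  std::vector<double> geE, giE, geI, giI;               // noise conductances
  // extrinsic stimulus gating (per E neuron)
  std::vector<double> extRate;                          // spikes/ms
  std::vector<double> extA, extX, extN;
  double g_extA = 0.0, g_extN = 0.0, extOnset = 0.0;
  // spatially non-selective input from an upstream circuit (AMPA only)
  double s_couple = 0.0, g_couple = 0.0;
  double iInjE = 0.0, iInjI = 0.0;
  std::vector<Pulse> pulses;

  // scratch
  std::vector<double> accA, accN;
  std::vector<int> spikesE, spikesI;                    // this step

  // precomputed decay factors
  double dAE, dAI, dGE, dGI, dX, dExtA;
  double eeE, AeE, eiE, AiE, eeI, AeI, eiI, AiI;

  void init(double dt_) {
    dt = dt_;
    vE.assign(E.n, 0.0); vI.assign(I.n, 0.0);
    refE.assign(E.n, 0.0); refI.assign(I.n, 0.0);
    sA_E.assign(E.n, 0.0); sA_I.assign(E.n, 0.0);
    xE.assign(E.n, 0.0); xI.assign(E.n, 0.0);
    sN_E.assign(E.n, 0.0); sN_I.assign(E.n, 0.0);
    sG_E.assign(I.n, 0.0); sG_I.assign(I.n, 0.0);
    geE.assign(E.n, nzE.ge0); giE.assign(E.n, nzE.gi0);
    geI.assign(I.n, nzI.ge0); giI.assign(I.n, nzI.gi0);
    extRate.assign(E.n, 0.0);
    extA.assign(E.n, 0.0); extX.assign(E.n, 0.0); extN.assign(E.n, 0.0);
    accA.assign(E.n, 0.0); accN.assign(E.n, 0.0);
    // desynchronized start: potentials spread between rest and threshold
    for (int i = 0; i < E.n; ++i)
      vE[i] = E.VL + (E.Vth - 2.0 - E.VL) * unif_rand();
    for (int i = 0; i < I.n; ++i)
      vI[i] = I.VL + (I.Vth - 2.0 - I.VL) * unif_rand();
    dAE = 1.0 - dt / onE.tauA;  dAI = 1.0 - dt / onI.tauA;
    dGE = 1.0 - dt / onE.tauG;  dGI = 1.0 - dt / onI.tauG;
    dX  = 1.0 - dt / taux;      dExtA = dAE;
    eeE = std::exp(-dt / nzE.taue);
    AeE = std::sqrt(nzE.De * nzE.taue / 2.0 * (1.0 - eeE * eeE));
    eiE = std::exp(-dt / nzE.taui);
    AiE = std::sqrt(nzE.Di * nzE.taui / 2.0 * (1.0 - eiE * eiE));
    eeI = std::exp(-dt / nzI.taue);
    AeI = std::sqrt(nzI.De * nzI.taue / 2.0 * (1.0 - eeI * eeI));
    eiI = std::exp(-dt / nzI.taui);
    AiI = std::sqrt(nzI.Di * nzI.taui / 2.0 * (1.0 - eiI * eiI));
  }

  // effective noise means at time t (control pulses rescale g_e0)
  void noise_means(double t, double& ge0E, double& ge0I) const {
    ge0E = nzE.ge0; ge0I = nzI.ge0;
    for (const Pulse& p : pulses) {
      if (t >= p.t0 && t < p.t1) {
        if (p.pop == 0) ge0E = p.factor * ref_ge0;
        else            ge0I = p.factor * ref_ge0;
      }
    }
  }

  void step(double t, double extra_current_E = 0.0) {
    const int nE = E.n, nI = I.n;
    spikesE.clear(); spikesI.clear();

    // recurrent weighted sums (E->E structured; everything else uniform)
    {
      const char* tr = "N"; const double one = 1.0, zero = 0.0;
      const int inc = 1;
      F77_CALL(dgemv)(tr, &nE, &nE, &one, W, &nE, sA_E.data(), &inc,
                      &zero, accA.data(), &inc FCONE);
      F77_CALL(dgemv)(tr, &nE, &nE, &one, W, &nE, sN_E.data(), &inc,
                      &zero, accN.data(), &inc FCONE);
    }
    double sumA_I = 0.0, sumN_I = 0.0, sumG_E = 0.0, sumG_I = 0.0;
    for (int j = 0; j < nE; ++j) { sumA_I += sA_I[j]; sumN_I += sN_I[j]; }
    for (int j = 0; j < nI; ++j) { sumG_E += sG_E[j]; sumG_I += sG_I[j]; }

    // pyramidal membrane update
    for (int i = 0; i < nE; ++i) {
      if (refE[i] > 0.0) { refE[i] -= dt; continue; }
      const double v = vE[i];
      const double B = mg_block(v, mg);
      double Isyn =
        onE.gA * accA[i] * (v - VE) +
        rho * onE.gN * B * accN[i] * (v - VE) +
        onE.gG * sumG_E * (v - VI) +
        std::max(geE[i], 0.0) * (v - VE) +
        std::max(giE[i], 0.0) * (v - VI) +
        g_extA * extA[i] * (v - VE) +
        g_extN * B * extN[i] * (v - VE) +
        g_couple * s_couple * (v - VE) -
        iInjE - extra_current_E;
      double vn = v + dt * (-E.gL * (v - E.VL) - Isyn) / E.Cm;
      if (vn >= E.Vth) {
        spikesE.push_back(i);
        vn = E.Vres;
        refE[i] = E.tref;
      }
      if (vn < -150.0 || vn > 100.0 || !std::isfinite(vn))
        stop("membrane potential diverged at t = %.3f ms (pyramidal %d); "
             "reduce dt", t, i + 1);
      vE[i] = vn;
    }
    // interneuron membrane update
    for (int i = 0; i < nI; ++i) {
      if (refI[i] > 0.0) { refI[i] -= dt; continue; }
      const double v = vI[i];
      const double B = mg_block(v, mg);
      double Isyn =
        onI.gA * sumA_I * (v - VE) +
        rho * onI.gN * B * sumN_I * (v - VE) +
        onI.gG * sumG_I * (v - VI) +
        std::max(geI[i], 0.0) * (v - VE) +
        std::max(giI[i], 0.0) * (v - VI) -
        iInjI;
      double vn = v + dt * (-I.gL * (v - I.VL) - Isyn) / I.Cm;
      if (vn >= I.Vth) {
        spikesI.push_back(i);
        vn = I.Vres;
        refI[i] = I.tref;
      }
      if (vn < -150.0 || vn > 100.0 || !std::isfinite(vn))
        stop("membrane potential diverged at t = %.3f ms (interneuron %d); "
             "reduce dt", t, i + 1);
      vI[i] = vn;
    }

    // synaptic gating: Euler decay, then this step's spikes
    for (int j = 0; j < nE; ++j) {
      sA_E[j] *= dAE; sA_I[j] *= dAI;
      sN_E[j] += dt * (-sN_E[j] / onE.tauN +
                       alpha * xE[j] * (1.0 - sN_E[j]));
      sN_I[j] += dt * (-sN_I[j] / onI.tauN +
                       alpha * xI[j] * (1.0 - sN_I[j]));
      if (sN_E[j] < 0.0) sN_E[j] = 0.0; else if (sN_E[j] > 1.0) sN_E[j] = 1.0;
      if (sN_I[j] < 0.0) sN_I[j] = 0.0; else if (sN_I[j] > 1.0) sN_I[j] = 1.0;
      xE[j] *= dX; xI[j] *= dX;
    }
    for (int s : spikesE) {
      sA_E[s] += 1.0; sA_I[s] += 1.0; xE[s] += 1.0; xI[s] += 1.0;
    }
    for (int j = 0; j < nI; ++j) { sG_E[j] *= dGE; sG_I[j] *= dGI; }
    for (int s : spikesI) { sG_E[s] += 1.0; sG_I[s] += 1.0; }

    // extrinsic Poisson stimulus (AMPA + NMDA, per E neuron)
    if (g_extA > 0.0 || g_extN > 0.0) {
      for (int i = 0; i < E.n; ++i) {
        extA[i] *= dExtA;
        extN[i] += dt * (-extN[i] / onE.tauN +
                         alpha * extX[i] * (1.0 - extN[i]));
        if (extN[i] < 0.0) extN[i] = 0.0;
        else if (extN[i] > 1.0) extN[i] = 1.0;
        extX[i] *= dX;
        if (t >= extOnset && extRate[i] > 0.0 &&
            unif_rand() < extRate[i] * dt) {
          extA[i] += 1.0; extX[i] += 1.0;
        }
      }
    }

    // background noise conductances (exact discrete OU update)
    double ge0E, ge0I;
    noise_means(t, ge0E, ge0I);
    for (int i = 0; i < E.n; ++i) {
      geE[i] = ge0E + (geE[i] - ge0E) * eeE + AeE * norm_rand();
      giE[i] = nzE.gi0 + (giE[i] - nzE.gi0) * eiE + AiE * norm_rand();
    }
    for (int i = 0; i < I.n; ++i) {
      geI[i] = ge0I + (geI[i] - ge0I) * eeI + AeI * norm_rand();
      giI[i] = nzI.gi0 + (giI[i] - nzI.gi0) * eiI + AiI * norm_rand();
    }
  }
};

Net build_net(const List& cfg, const NumericMatrix& W) {
  Net net;
  List pops = cfg["populations"], syn = cfg["synapses"],
       noise = cfg["noise"], con = cfg["connectivity"];
  net.E = as_pop(pops["pyramidal"]);
  net.I = as_pop(pops["interneuron"]);
  net.onE = as_syn(syn["onto_pyramidal"]);
  net.onI = as_syn(syn["onto_interneuron"]);
  net.nzE = as_noise(noise["pyramidal"]);
  net.nzI = as_noise(noise["interneuron"]);
  net.VE = as<double>(syn["excitatory_reversal"]);
  net.VI = as<double>(syn["inhibitory_reversal"]);
  net.mg = as<double>(syn["magnesium_mM"]);
  net.alpha = as<double>(syn["nmda_saturation_rate"]);
  net.taux = as<double>(syn["nmda_rise_time_constant"]);
  net.rho = as<double>(con["rho"]);
  net.ref_ge0 = as<double>(noise["reference_exc_conductance"]);
  if (W.nrow() != net.E.n || W.ncol() != net.E.n)
    stop("weight matrix dimensions do not match the pyramidal population");
  net.W = W.begin();
  return net;
}

void apply_protocol(Net& net, const List& proto) {
  if (proto.containsElementNamed("i_inject_pyramidal"))
    net.iInjE = as<double>(proto["i_inject_pyramidal"]);
  if (proto.containsElementNamed("i_inject_interneuron"))
    net.iInjI = as<double>(proto["i_inject_interneuron"]);
  if (proto.containsElementNamed("pulses")) {
    NumericMatrix pm = proto["pulses"];
    for (int r = 0; r < pm.nrow(); ++r) {
      Pulse p;
      p.pop = (int)pm(r, 0); p.t0 = pm(r, 1); p.t1 = pm(r, 2);
      p.factor = pm(r, 3);
      net.pulses.push_back(p);
    }
  }
  if (proto.containsElementNamed("stimulus_rate")) {
    NumericVector rt = proto["stimulus_rate"];   // spikes/ms per E neuron
    if (rt.size() != net.E.n)
      stop("stimulus_rate must have one entry per pyramidal neuron");
    for (int i = 0; i < net.E.n; ++i) net.extRate[i] = rt[i];
    net.g_extA = as<double>(proto["g_ext_ampa"]);
    net.g_extN = as<double>(proto["g_ext_nmda"]);
    if (proto.containsElementNamed("stimulus_onset"))
      net.extOnset = as<double>(proto["stimulus_onset"]);
  }
}

// Online population SDF: the rise-and-decay kernel
// k(u) = exp(-u/tau_d) - exp(-u/tau_c), tau_c = tau_g tau_d/(tau_g+tau_d),
// maintained by two leaky accumulators; integral of k is tau_d - tau_c, so
// rate_Hz = 1000 (a - b) / ((tau_d - tau_c) n_members).
struct PopSdf {
  std::vector< std::vector<int> > members;  // E indices per population
  std::vector<char> isMember;               // flattened membership flags
  std::vector<double> a, b;
  double taud, tauc, da, db, norm;
  int npop, nE;

  void init(const List& sets, int nE_, double taug, double taud_, double dt) {
    nE = nE_;
    npop = sets.size();
    taud = taud_;
    tauc = taug * taud / (taug + taud);
    da = std::exp(-dt / taud);
    db = std::exp(-dt / tauc);
    a.assign(npop, 0.0); b.assign(npop, 0.0);
    isMember.assign((size_t)npop * nE, 0);
    for (int p = 0; p < npop; ++p) {
      IntegerVector idx = sets[p];
      std::vector<int> m;
      for (int k = 0; k < idx.size(); ++k) {
        m.push_back(idx[k]);
        isMember[(size_t)p * nE + idx[k]] = 1;
      }
      members.push_back(m);
    }
  }

  void advance(const std::vector<int>& spikesE) {
    for (int p = 0; p < npop; ++p) { a[p] *= da; b[p] *= db; }
    for (int s : spikesE)
      for (int p = 0; p < npop; ++p)
        if (isMember[(size_t)p * nE + s]) { a[p] += 1.0; b[p] += 1.0; }
  }

  double rate(int p) const {
    return 1000.0 * (a[p] - b[p]) / ((taud - tauc) * members[p].size());
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_simulate_network(List cfg, NumericMatrix W, double duration,
                          List protocol, List sdf_pops, double sdf_taug,
                          double sdf_taud, double stop_threshold) {
  Net net = build_net(cfg, W);
  double dt = as<double>(as<List>(cfg["integration"])["dt"]);
  RNGScope rng;
  net.init(dt);
  apply_protocol(net, protocol);

  PopSdf sdf;
  bool track = sdf_pops.size() > 0;
  if (track) sdf.init(sdf_pops, net.E.n, sdf_taug, sdf_taud, dt);

  const int n_steps = (int)std::ceil(duration / dt);
  std::vector<int> spk_id; std::vector<double> spk_t;
  int n_samples = (int)std::floor(duration) + 1;
  NumericMatrix sdf_out(track ? n_samples : 0, track ? (int)sdf_pops.size() : 0);
  int crossed_pop = -1; double crossed_t = NA_REAL;
  double next_sample = 0.0; int sample_i = 0;
  double t_end = duration;

  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;
    net.step(t);
    for (int id : net.spikesE) { spk_id.push_back(id); spk_t.push_back(t + dt); }
    for (int id : net.spikesI) {
      spk_id.push_back(net.E.n + id); spk_t.push_back(t + dt);
    }
    if (track) {
      sdf.advance(net.spikesE);
      if (t + dt >= next_sample - 1e-9 && sample_i < n_samples) {
        for (int p = 0; p < sdf.npop; ++p) {
          double r = sdf.rate(p);
          sdf_out(sample_i, p) = r;
          if (crossed_pop < 0 && stop_threshold > 0 && r >= stop_threshold) {
            crossed_pop = p; crossed_t = next_sample;
          }
        }
        ++sample_i; next_sample += 1.0;
        if (crossed_pop >= 0 && stop_threshold > 0) { t_end = t + dt; break; }
      }
    }
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["neuron"] = wrap(spk_id), _["time"] = wrap(spk_t),
    _["duration"] = t_end, _["n_pyramidal"] = net.E.n,
    _["n_interneuron"] = net.I.n);
  if (track) {
    out["sdf"] = sdf_out;
    out["n_samples"] = sample_i;
    out["crossed_pop"] = crossed_pop + 1;   // 1-based; 0 if none
    out["crossed_t"] = crossed_t;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_simulate_coupled(List cfg_timing, NumericMatrix W_timing,
                          List cfg_decision, NumericMatrix W_decision,
                          double duration, List proto_timing,
                          List proto_decision, double g_couple,
                          List sdf_pops_decision, List sdf_pops_timing,
                          double sdf_taug, double sdf_taud,
                          double stop_threshold, double watch_from) {
  Net tn = build_net(cfg_timing, W_timing);
  Net dn = build_net(cfg_decision, W_decision);
  double dt = as<double>(as<List>(cfg_timing["integration"])["dt"]);
  double dtd = as<double>(as<List>(cfg_decision["integration"])["dt"]);
  if (std::abs(dt - dtd) > 1e-12)
    stop("coupled networks must share one integration step");
  RNGScope rng;
  tn.init(dt);
  dn.init(dt);
  apply_protocol(tn, proto_timing);
  apply_protocol(dn, proto_decision);
  dn.g_couple = g_couple;
  double dCpl = 1.0 - dt / dn.onE.tauA;   // coupling gating: AMPA kinetics

  PopSdf sdfD, sdfT;
  bool trackD = sdf_pops_decision.size() > 0;
  bool trackT = sdf_pops_timing.size() > 0;
  if (trackD) sdfD.init(sdf_pops_decision, dn.E.n, sdf_taug, sdf_taud, dt);
  if (trackT) sdfT.init(sdf_pops_timing, tn.E.n, sdf_taug, sdf_taud, dt);

  const int n_steps = (int)std::ceil(duration / dt);
  std::vector<int> spk_idT, spk_idD;
  std::vector<double> spk_tT, spk_tD;
  int n_samples = (int)std::floor(duration) + 1;
  NumericMatrix sdfD_out(trackD ? n_samples : 0,
                         trackD ? (int)sdf_pops_decision.size() : 0);
  NumericMatrix sdfT_out(trackT ? n_samples : 0,
                         trackT ? (int)sdf_pops_timing.size() : 0);
  int crossed_pop = -1; double crossed_t = NA_REAL;
  double next_sample = 0.0; int sample_i = 0;
  double t_end = duration;

  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;
    tn.step(t);
    dn.step(t);
    // coupling: decision-network gating driven by all timing E spikes
    dn.s_couple = dn.s_couple * dCpl + tn.spikesE.size();
    for (int id : tn.spikesE) { spk_idT.push_back(id); spk_tT.push_back(t + dt); }
    for (int id : tn.spikesI) {
      spk_idT.push_back(tn.E.n + id); spk_tT.push_back(t + dt);
    }
    for (int id : dn.spikesE) { spk_idD.push_back(id); spk_tD.push_back(t + dt); }
    for (int id : dn.spikesI) {
      spk_idD.push_back(dn.E.n + id); spk_tD.push_back(t + dt);
    }
    if (trackD) sdfD.advance(dn.spikesE);
    if (trackT) sdfT.advance(tn.spikesE);
    if ((trackD || trackT) && t + dt >= next_sample - 1e-9 &&
        sample_i < n_samples) {
      if (trackD) {
        // all populations are evaluated at the sample; simultaneous
        // crossings are broken by the higher SDF, exact ties by coin flip
        int best = -1; double bestr = 0.0;
        for (int p = 0; p < sdfD.npop; ++p) {
          double r = sdfD.rate(p);
          sdfD_out(sample_i, p) = r;
          if (stop_threshold > 0 && next_sample >= watch_from &&
              r >= stop_threshold) {
            if (best < 0 || r > bestr ||
                (r == bestr && unif_rand() < 0.5)) { best = p; bestr = r; }
          }
        }
        if (crossed_pop < 0 && best >= 0) {
          crossed_pop = best; crossed_t = next_sample;
        }
      }
      if (trackT)
        for (int p = 0; p < sdfT.npop; ++p)
          sdfT_out(sample_i, p) = sdfT.rate(p);
      ++sample_i; next_sample += 1.0;
      if (crossed_pop >= 0 && stop_threshold > 0) { t_end = t + dt; break; }
    }
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["timing"] = List::create(
      _["neuron"] = wrap(spk_idT), _["time"] = wrap(spk_tT),
      _["duration"] = t_end, _["n_pyramidal"] = tn.E.n,
      _["n_interneuron"] = tn.I.n, _["sdf"] = sdfT_out),
    _["decision"] = List::create(
      _["neuron"] = wrap(spk_idD), _["time"] = wrap(spk_tD),
      _["duration"] = t_end, _["n_pyramidal"] = dn.E.n,
      _["n_interneuron"] = dn.I.n, _["sdf"] = sdfD_out),
    _["n_samples"] = sample_i,
    _["crossed_pop"] = crossed_pop + 1,
    _["crossed_t"] = crossed_t);
}

// Reference trace of one synaptic gating variable under a given spike
// train, using exactly the update scheme of the network integrator.
// type 0: single-exponential (AMPA/GABA); type 1: saturating NMDA,
// returning both s and the auxiliary rise variable x.
// [[Rcpp::export]]
NumericMatrix cpp_gating_trace(NumericVector spike_times, double duration,
                               double dt, double tau_decay, double tau_rise,
                               double alpha, int type) {
  int n_steps = (int)std::ceil(duration / dt);
  NumericMatrix out(n_steps + 1, type == 1 ? 3 : 2);
  double s = 0.0, x = 0.0;
  int k = 0;
  out(0, 0) = 0.0; out(0, 1) = 0.0;
  std::vector<int> spike_step;
  for (double ts : spike_times)
    spike_step.push_back((int)std::floor(ts / dt + 0.5));
  for (int i = 0; i < n_steps; ++i) {
    if (type == 0) {
      s *= (1.0 - dt / tau_decay);
    } else {
      s += dt * (-s / tau_decay + alpha * x * (1.0 - s));
      if (s < 0.0) s = 0.0; else if (s > 1.0) s = 1.0;
      x *= (1.0 - dt / tau_rise);
    }
    for (size_t j = k; j < spike_step.size() && spike_step[j] == i; ++j, ++k) {
      if (type == 0) s += 1.0; else x += 1.0;
    }
    out(i + 1, 0) = (i + 1) * dt;
    out(i + 1, 1) = s;
    if (type == 1) out(i + 1, 2) = x;
  }
  return out;
}

// Reference trace of one point-conductance noise channel (exact OU update).
// [[Rcpp::export]]
NumericVector cpp_noise_trace(int n_steps, double dt, double g0, double tau,
                              double D) {
  RNGScope rng;
  NumericVector g(n_steps + 1);
  double e = std::exp(-dt / tau);
  double A = std::sqrt(D * tau / 2.0 * (1.0 - e * e));
  g[0] = g0;
  for (int i = 0; i < n_steps; ++i)
    g[i + 1] = g0 + (g[i] - g0) * e + A * norm_rand();
  return g;
}

// Euler-Maruyama first-passage times of dz = lambda z dt + sigma dW from
// z0 to theta. Paths that have not crossed by `horizon` return NA.
// [[Rcpp::export]]
NumericVector cpp_ou_first_passage(int n_paths, double z0, double theta,
                                   double lambda, double sigma, double dt,
                                   double horizon) {
  RNGScope rng;
  NumericVector out(n_paths);
  int n_steps = (int)std::ceil(horizon / dt);
  double sq = sigma * std::sqrt(dt);
  for (int p = 0; p < n_paths; ++p) {
    double z = z0, tcross = NA_REAL;
    for (int s = 0; s < n_steps; ++s) {
      z += lambda * z * dt + sq * norm_rand();
      if (z >= theta) { tcross = (s + 1) * dt; break; }
    }
    out[p] = tcross;
    if (p % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
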