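// Three-circuit leaky integrate-and-fire network with conductance-free
// difference-of-exponential synapses and an LFP proxy (sum over pyramidal
// cells of |I_AMPA| + |I_GABA|).
//
// Integration is exponential-Euler per linear ODE (exact between spike
// deliveries for the piecewise-linear cascade); spikes are delivered on the
// step grid through circular delay buffers. All randomness comes from R's
// RNG, so set.seed() in R makes runs bit-reproducible.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Connectivity {
  int M, N, n_exc;
  // intra-circuit adjacency: per (global) sender, global target indices
  std::vector<std::vector<int>> intra;
  // inter-circuit: per sender, targets and precomputed x_A jumps
  std::vector<std::vector<int>> inter;
  std::vector<std::vector<double>> inter_jump;
};

inline bool is_exc(int global, int N, int n_exc) { return (global % N) < n_exc; }

// Draw order is fixed (circuit-major, sender-major) so that the same R seed
// reproduces the same wiring in both the exposed connectivity builder and
// the simulator.
Connectivity build_conn(const IntegerMatrix &adj, int N, double frac_exc,
                        double p_intra, double p_inter,
                        const NumericVector &j_int_edges,
                        const NumericVector &tau_m, double tau_rA) {
  Connectivity c;
  c.M = adj.nrow();
  c.N = N;
  c.n_exc = (int)std::lround(frac_exc * N);
  int total = c.M * N;
  c.intra.assign(total, {});
  c.inter.assign(total, {});
  c.inter_jump.assign(total, {});
  for (int circ = 0; circ < c.M; ++circ) {
    int base = circ * N;
    for (int j = 0; j < N; ++j) {
      std::vector<int> &tg = c.intra[base + j];
      for (int i = 0; i < N; ++i) {
        if (i == j) continue;
        if (unif_rand() < p_intra) tg.push_back(base + i);
      }
    }
  }
  // inter-circuit projections, row-major over present edges
  int edge_idx = 0;
  for (int a = 0; a < c.M; ++a) {
    for (int b = 0; b < c.M; ++b) {
      if (a == b || adj(a, b) == 0) continue;
      double J = j_int_edges[edge_idx++];
      for (int j = 0; j < c.n_exc; ++j) {
        int sender = a * N + j;
        for (int i = 0; i < N; ++i) {
          if (unif_rand() < p_inter) {
            int tgt = b * N + i;
            c.inter[sender].push_back(tgt);
            int cls = (i < c.n_exc) ? 0 : 1;
            c.inter_jump[sender].push_back(tau_m[cls] * J / tau_rA);
          }
        }
      }
    }
  }
  return c;
}

} // namespace

// [[Rcpp::export]]
List lif_connectivity_cpp(IntegerMatrix adj, int n_neurons, double frac_exc,
                          double p_intra, double p_inter,
                          NumericVector j_int_edges, NumericVector tau_m,
                          double tau_rA, bool return_edges) {
  Connectivity c = build_conn(adj, n_neurons, frac_exc, p_intra, p_inter,
                              j_int_edges, tau_m, tau_rA);
  IntegerVector intra_counts(c.M);
  for (int circ = 0; circ < c.M; ++circ) {
    long cnt = 0;
    for (int j = 0; j < c.N; ++j) cnt += c.intra[circ * c.N + j].size();
    intra_counts[circ] = (int)cnt;
  }
  long n_inter = 0;
  for (size_t j = 0; j < c.inter.size(); ++j) n_inter += c.inter[j].size();
  List out = List::create(_["intra_counts"] = intra_counts,
                          _["n_inter"] = (double)n_inter,
                          _["n_exc"] = c.n_exc);
  if (return_edges) {
    std::vector<int> snd, tgt;
    for (int j = 0; j < c.M * c.N; ++j)
      for (size_t k = 0; k < c.inter[j].size(); ++k) {
        snd.push_back(j + 1);
        tgt.push_back(c.inter[j][k] + 1);
      }
    out["inter_sender"] = wrap(snd);
    out["inter_target"] = wrap(tgt);
  }
  return out;
}

// [[Rcpp::export]]
List lif_simulate_cpp(IntegerMatrix adj, int n_neurons, double frac_exc,
                      double p_intra, double p_inter,
                      NumericVector tau_m,   // (exc, inh) membrane, ms
                      double v_thr, double v_res,
                      NumericVector tau_rp,  // (exc, inh) refractory, ms
                      double tau_rA, double tau_dA, double tau_rG, double tau_dG,
                      double tau_L, double tau_L_int,
                      NumericVector j_exc,   // recurrent AMPA efficacy onto (exc, inh)
                      NumericVector j_inh,   // recurrent GABA efficacy onto (exc, inh)
                      NumericVector j_ext,   // external AMPA efficacy onto (exc, inh)
                      NumericVector j_int_edges,
                      NumericMatrix ext_rate, // M x n_steps, spikes/ms
                      double dt, double duration, double lfp_dt,
                      double v_init,
                      NumericVector ext_spike_times,
                      bool use_poisson_ext,
                      bool record_v, bool record_spikes) {
  const int M = adj.nrow();
  const int N = n_neurons;
  const int total = M * N;
  const int n_steps = (int)std::lround(duration / dt);
  const int lfp_every = (int)std::lround(lfp_dt / dt);
  const int n_lfp = n_steps / lfp_every;
  if (ext_rate.ncol() < n_steps) stop("ext_rate has too few timesteps");

  Connectivity conn = build_conn(adj, N, frac_exc, p_intra, p_inter,
                                 j_int_edges, tau_m, tau_rA);
  const int n_exc = conn.n_exc;

  // per-class precomputations
  double em[2] = {std::exp(-dt / tau_m[0]), std::exp(-dt / tau_m[1])};
  int rp_steps[2] = {(int)std::lround(tau_rp[0] / dt), (int)std::lround(tau_rp[1] / dt)};
  // x_A jumps per (sender exc) onto target class; x_G jumps for inh senders
  double jump_A[2] = {tau_m[0] * j_exc[0] / tau_rA, tau_m[1] * j_exc[1] / tau_rA};
  double jump_G[2] = {tau_m[0] * j_inh[0] / tau_rG, tau_m[1] * j_inh[1] / tau_rG};
  double jump_ext[2] = {tau_m[0] * j_ext[0] / tau_rA, tau_m[1] * j_ext[1] / tau_rA};

  // exact two-exponential cascade propagators over one step
  const double erA = std::exp(-dt / tau_rA), edA = std::exp(-dt / tau_dA);
  const double erG = std::exp(-dt / tau_rG), edG = std::exp(-dt / tau_dG);
  const double cA = tau_rA / (tau_rA - tau_dA);  // x-to-I coupling, AMPA
  const double cG = tau_rG / (tau_rG - tau_dG);

  std::vector<double> V(total, v_init), IA(total, 0), xA(total, 0),
      IG(total, 0), xG(total, 0);
  std::vector<int> refrac(total, 0);
  std::vector<unsigned char> cls(total);
  for (int g = 0; g < total; ++g) cls[g] = is_exc(g, N, n_exc) ? 0 : 1;

  const int d_intra = std::max(1, (int)std::lround(tau_L / dt));
  const int d_inter = std::max(1, (int)std::lround(tau_L_int / dt));
  const int ring_sz = std::max(d_intra, d_inter) + 1;
  std::vector<std::vector<int>> ring_intra(ring_sz), ring_inter(ring_sz);

  // deterministic external spikes (test hook): step at which each pulse lands
  std::vector<int> ext_pulse_steps;
  for (int k = 0; k < ext_spike_times.size(); ++k)
    ext_pulse_steps.push_back((int)std::lround(ext_spike_times[k] / dt) + d_intra);

  NumericMatrix lfp(M, n_lfp);
  NumericMatrix v_trace;
  if (record_v) v_trace = NumericMatrix(M, n_lfp);
  std::vector<int> spike_neuron;
  std::vector<double> spike_time;

  for (int s = 0; s < n_steps; ++s) {
    // 1. deliver due spikes
    int slot = s % ring_sz;
    for (int snd : ring_intra[slot]) {
      if (cls[snd] == 0) {
        for (int tgt : conn.intra[snd]) xA[tgt] += jump_A[cls[tgt]];
      } else {
        for (int tgt : conn.intra[snd]) xG[tgt] += jump_G[cls[tgt]];
      }
    }
    ring_intra[slot].clear();
    for (int snd : ring_inter[slot]) {
      const std::vector<int> &tg = conn.inter[snd];
      const std::vector<double> &jp = conn.inter_jump[snd];
      for (size_t k = 0; k < tg.size(); ++k) xA[tg[k]] += jp[k];
    }
    ring_inter[slot].clear();

    // 2. external input
    if (use_poisson_ext) {
      for (int circ = 0; circ < M; ++circ) {
        double lambda = N * ext_rate(circ, s) * dt;
        if (lambda <= 0) continue;
        int nev = (int)R::rpois(lambda);
        int base = circ * N;
        for (int k = 0; k < nev; ++k) {
          int i = (int)(unif_rand() * N);
          if (i >= N) i = N - 1;
          xA[base + i] += jump_ext[cls[base + i]];
        }
      }
    }
    for (int ps : ext_pulse_steps)
      if (ps == s)
        for (int g = 0; g < total; ++g) xA[g] += jump_ext[cls[g]];

    // 3a. synaptic cascade (branch-free, auto-vectorizable)
    double *RIA = IA.data(), *RxA = xA.data(), *RIG = IG.data(), *RxG = xG.data();
    for (int g = 0; g < total; ++g) {
      double aA = RxA[g] * cA;
      RIA[g] = (RIA[g] - aA) * edA + aA * erA;
      RxA[g] *= erA;
      double aG = RxG[g] * cG;
      RIG[g] = (RIG[g] - aG) * edG + aG * erG;
      RxG[g] *= erG;
    }
    // 3b. membrane update + threshold/reset/refractory
    for (int g = 0; g < total; ++g) {
      if (refrac[g] > 0) {
        --refrac[g];
        V[g] = v_res;
        continue;
      }
      double e = em[cls[g]];
      V[g] = V[g] * e + (RIA[g] - RIG[g]) * (1.0 - e);
      if (V[g] >= v_thr) {
        V[g] = v_res;
        refrac[g] = rp_steps[cls[g]];
        ring_intra[(s + d_intra) % ring_sz].push_back(g);
        if (!conn.inter[g].empty())
          ring_inter[(s + d_inter) % ring_sz].push_back(g);
        if (record_spikes) {
          spike_neuron.push_back(g + 1);
          spike_time.push_back((s + 1) * dt);
        }
      }
    }

    // 4. LFP sample at the end of each lfp_dt interval
    if ((s + 1) % lfp_every == 0) {
      int tick = (s + 1) / lfp_every - 1;
      for (int circ = 0; circ < M; ++circ) {
        double acc = 0;
        int base = circ * N;
        for (int i = 0; i < n_exc; ++i)
          acc += std::fabs(IA[base + i]) + std::fabs(IG[base + i]);
        lfp(circ, tick) = acc;
        if (record_v) v_trace(circ, tick) = V[base];
      }
      if (!R_finite(lfp(0, tick)))
        stop("numerical divergence at step %d (t = %.2f ms)", s + 1, (s + 1) * dt);
    }
  }

  List out = List::create(_["lfp"] = lfp, _["n_exc"] = n_exc,
                          _["n_steps"] = n_steps);
  if (record_v) out["v"] = v_trace;
  if (record_spikes) {
    out["spike_neuron"] = wrap(spike_neuron);
    out["spike_time"] = wrap(spike_time);
  }
  return out;
}
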