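#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Leaky integrate-and-fire population driven by per-cell currents sampled
// at movie-frame resolution (linearly interpolated to the integration step)
// plus white current noise.  Uses R's RNG so set.seed() controls the run.
//
// drive: ncells x nframes (nA); R_mohm in megaohm so R*I is in mV.
// noise_sd is the SD of the noise current in nA per sqrt(ms).
// [[Rcpp::export]]
List lif_population_cpp(NumericMatrix drive, double frame_dt_ms, double dt_ms,
                        int n_steps, double tau_m, double r_mohm,
                        double e_l, double v_thr, double v_reset,
                        double t_ref_ms, double noise_sd) {
  const int n = drive.nrow();
  const int nframes = drive.ncol();
  std::vector<double> v(n, e_l);
  std::vector<int> refr(n, 0);
  const int ref_steps = (int)std::ceil(t_ref_ms / dt_ms);
  std::vector<int> spike_cell, spike_step;
  const double sq = std::sqrt(dt_ms);
  RNGScope scope;
  for (int s = 0; s < n_steps; ++s) {
    double tf = s * dt_ms / frame_dt_ms;
    int f0 = (int)tf;
    if (f0 >= nframes - 1) f0 = nframes - 2;
    if (f0 < 0) f0 = 0;
    double w1 = tf - f0;
    if (w1 < 0) w1 = 0; if (w1 > 1) w1 = 1;
    for (int i = 0; i < n; ++i) {
      if (refr[i] > 0) { --refr[i]; continue; }
      double I = (1.0 - w1) * drive(i, f0) + w1 * drive(i, f0 + 1);
      double eta = noise_sd > 0 ? noise_sd * norm_rand() : 0.0;
      v[i] += dt_ms / tau_m * (-(v[i] - e_l) + r_mohm * I)
            + r_mohm * eta * sq / tau_m;
      if (v[i] >= v_thr) {
        spike_cell.push_back(i + 1);
        spike_step.push_back(s);
        v[i] = v_reset;
        refr[i] = ref_steps;
      }
    }
  }
  return List::create(_["cell"] = wrap(spike_cell),
                      _["step"] = wrap(spike_step));
}

// Tsodyks-Markram depression recursion: released fraction u*x at each
// presynaptic spike time, with resources recovering between spikes as
// x(t) = 1 - (1 - x+) exp(-dt/tau_rec) and x+ = x(1-u) after release.
// This is the same update the network integrator applies per source.
// [[Rcpp::export]]
NumericVector tm_release_cpp(NumericVector spike_times_ms, double u,
                             double tau_rec) {
  int n = spike_times_ms.size();
  NumericVector rel(n);
  double x = 1.0, last = -1e18;
  for (int i = 0; i < n; ++i) {
    double xr = 1.0 - (1.0 - x) * std::exp(-(spike_times_ms[i] - last) / tau_rec);
    rel[i] = u * xr;
    x = xr * (1.0 - u);
    last = spike_times_ms[i];
  }
  return rel;
}

// Conductance-based exponential integrate-and-fire network with
// exponentially decaying synapses and Tsodyks-Markram short-term
// depression (fixed utilisation u, per-synapse resource variable updated
// at presynaptic spike times).
//
// Sources are the N cortical neurons followed by M external (LGN) sources
// whose spike trains are supplied as inputs.  Synapses are stored CSR by
// source.  Weights in nS, membrane resistance in megaohm (R*g*1e-3 is
// dimensionless), delays in integration steps (>= 1).
// [[Rcpp::export]]
List eif_network_cpp(int n_neurons,
                     NumericVector tau_m, NumericVector r_mohm,
                     NumericVector e_l, NumericVector v_t,
                     IntegerVector t_ref_steps,
                     double delta_t, double v_spike, double v_reset,
                     double e_exc, double e_inh,
                     double tau_syn_exc, double tau_syn_inh,
                     IntegerVector out_ptr, IntegerVector syn_tgt,
                     NumericVector syn_w, IntegerVector syn_delay,
                     NumericVector src_tau_rec, LogicalVector src_is_inh,
                     double stp_u,
                     IntegerVector ext_step, IntegerVector ext_src,
                     double dt_ms, int n_steps,
                     IntegerVector record_idx, int record_every,
                     NumericVector i_ext_na, NumericVector g_ext_exc_ns,
                     NumericVector v_init) {
  const int N = n_neurons;
  const int n_src = out_ptr.size() - 1;
  const int n_syn = syn_tgt.size();
  std::vector<double> v(v_init.begin(), v_init.end());
  std::vector<double> ge(N, 0.0), gi(N, 0.0);
  std::vector<int> refr(N, 0);
  // TM resources per source: all outgoing synapses of a source share the
  // same recovery constant and spike history, so one state suffices
  std::vector<double> x(n_src, 1.0);
  std::vector<double> last_spk(n_src, -1e18);
  (void)n_syn;
  int max_delay = 1;
  for (int k = 0; k < n_syn; ++k)
    if (syn_delay[k] > max_delay) max_delay = syn_delay[k];
  const int nbuf = max_delay + 1;
  std::vector<double> bufE((size_t)nbuf * N, 0.0);
  std::vector<double> bufI((size_t)nbuf * N, 0.0);
  const double dec_e = std::exp(-dt_ms / tau_syn_exc);
  const double dec_i = std::exp(-dt_ms / tau_syn_inh);
  std::vector<int> spike_cell, spike_step;
  const int n_rec = record_idx.size();
  const int n_rec_steps = n_rec > 0 ? (n_steps + record_every - 1) / record_every : 0;
  NumericMatrix vm(n_rec_steps, n_rec);
  int ext_pos = 0;
  const int n_ext = ext_step.size();

  auto deliver = [&](int src, int step_now) {
    double t_now = step_now * dt_ms;
    double dtp = t_now - last_spk[src];
    double xr = 1.0 - (1.0 - x[src]) * std::exp(-dtp / src_tau_rec[src]);
    x[src] = xr * (1.0 - stp_u);
    last_spk[src] = t_now;
    const double rel = stp_u * xr;
    double *bp = src_is_inh[src] ? bufI.data() : bufE.data();
    const int cur = step_now % nbuf;
    for (int k = out_ptr[src]; k < out_ptr[src + 1]; ++k) {
      int slot = cur + syn_delay[k];
      if (slot >= nbuf) slot -= nbuf;
      bp[(size_t)slot * N + syn_tgt[k]] += syn_w[k] * rel;
    }
  };

  for (int s = 0; s < n_steps; ++s) {
    // external source spikes scheduled for this step
    while (ext_pos < n_ext && ext_step[ext_pos] == s) {
      deliver(N + ext_src[ext_pos], s);
      ++ext_pos;
    }
    // conductance decay + arrival of delayed increments
    double *be = bufE.data() + (size_t)(s % nbuf) * N;
    double *bi = bufI.data() + (size_t)(s % nbuf) * N;
    for (int i = 0; i < N; ++i) {
      ge[i] = ge[i] * dec_e + be[i];
      gi[i] = gi[i] * dec_i + bi[i];
      be[i] = 0.0;
      bi[i] = 0.0;
    }
    // membrane update
    for (int i = 0; i < N; ++i) {
      if (refr[i] > 0) { --refr[i]; v[i] = v_reset; continue; }
      double arg = (v[i] - v_t[i]) / delta_t;
      if (arg > 30.0) arg = 30.0;  // clamp: spike detection guaranteed below
      // far below threshold the exponential term is numerically zero
      double ex = arg > -12.0 ? delta_t * std::exp(arg) : 0.0;
      double dv = -(v[i] - e_l[i]) + ex
        + r_mohm[i] * (1e-3 * ((ge[i] + g_ext_exc_ns[i]) * (e_exc - v[i])
                               + gi[i] * (e_inh - v[i])) + i_ext_na[i]);
      v[i] += dt_ms / tau_m[i] * dv;
      if (v[i] >= v_spike) {
        spike_cell.push_back(i + 1);
        spike_step.push_back(s);
        deliver(i, s);
        v[i] = v_reset;
        refr[i] = t_ref_steps[i];
      }
    }
    if (n_rec > 0 && s % record_every == 0) {
      int row = s / record_every;
      for (int j = 0; j < n_rec; ++j) vm(row, j) = v[record_idx[j]];
    }
  }
  return List::create(_["cell"] = wrap(spike_cell),
                      _["step"] = wrap(spike_step),
                      _["vm"] = vm);
}
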