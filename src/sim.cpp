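#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of a mixed network of GLIF (spiking) and
// leaky-integrator (non-spiking) neurons with conductance-based synapses.
//
// Units: ms, mV (above rest), nA, nF, uS.
//
// Update order within a step: (1) Euler-update all U and theta from the
// state at the start of the step; (2) exact exponential decay of spiking
// synapse conductances; (3) threshold detection U >= theta on GLIF
// neurons; (4) resets: U <- 0 (+ optional Gaussian reset noise) and
// outgoing spiking conductances <- Gmax.  A conductance set at a spike
// first drives the post-synaptic neuron on the next step (one dt of
// synaptic latency, vanishing as dt -> 0).
//
// Reset noise is drawn from R's RNG so that set.seed() in R makes runs
// bit-reproducible.

// [[Rcpp::export]]
List sim_core_cpp(IntegerVector n_spiking,  // 1 = GLIF, 0 = non-spiking
                  NumericVector Cmem, NumericVector Gmem,
                  NumericVector Ibias, NumericVector theta0,
                  NumericVector tau_theta, NumericVector m,
                  IntegerVector s_pre,      // 0-based
                  IntegerVector s_post,     // 0-based
                  IntegerVector s_spiking,  // 1 = spiking, 0 = graded
                  NumericVector s_Gmax, NumericVector s_tau,
                  NumericVector s_Es, NumericVector s_R,
                  NumericMatrix stim,       // cols: neuron(0-based), t0, t1, amp
                  double dt, double duration, double t_start,
                  NumericVector U0, NumericVector theta_init,
                  NumericVector Gs0,
                  double reset_noise_sd,
                  int record_every, bool record_gs,
                  double guard) {
  const int n = Cmem.size();
  const int ns = s_pre.size();
  const int nstim = stim.nrow();
  const long nstep = (long)std::floor(duration / dt + 0.5);

  std::vector<double> U(U0.begin(), U0.end());
  std::vector<double> th(theta_init.begin(), theta_init.end());
  std::vector<double> Gs(Gs0.begin(), Gs0.end());

  std::vector<double> decay(ns);
  for (int s = 0; s < ns; ++s)
    decay[s] = s_spiking[s] ? std::exp(-dt / s_tau[s]) : 1.0;

  // outgoing spiking synapses per neuron
  std::vector< std::vector<int> > outgoing(n);
  for (int s = 0; s < ns; ++s)
    if (s_spiking[s]) outgoing[s_pre[s]].push_back(s);

  const long nsamp = nstep / record_every + 1;
  NumericVector t_out(nsamp);
  NumericMatrix U_out(nsamp, n), th_out(nsamp, n);
  NumericMatrix Gs_out = record_gs ? NumericMatrix(nsamp, ns)
                                   : NumericMatrix(1, 1);
  std::vector< std::vector<double> > spikes(n);
  std::vector< std::vector<double> > spike_theta(n);

  long isamp = 0;
  t_out[0] = t_start;
  for (int i = 0; i < n; ++i) { U_out(0, i) = U[i]; th_out(0, i) = th[i]; }
  if (record_gs) for (int s = 0; s < ns; ++s) Gs_out(0, s) = Gs[s];
  ++isamp;

  std::vector<double> Iapp(n), Isyn(n), dU(n), dth(n);

  for (long k = 0; k < nstep; ++k) {
    const double t = t_start + k * dt;

    for (int i = 0; i < n; ++i) Iapp[i] = 0.0;
    for (int r = 0; r < nstim; ++r) {
      if (t >= stim(r, 1) && t < stim(r, 2))
        Iapp[(int)stim(r, 0)] += stim(r, 3);
    }

    for (int i = 0; i < n; ++i) Isyn[i] = 0.0;
    for (int s = 0; s < ns; ++s) {
      double g;
      if (s_spiking[s]) {
        g = Gs[s];
      } else {
        double a = U[s_pre[s]] / s_R[s];
        if (a < 0.0) a = 0.0; else if (a > 1.0) a = 1.0;
        g = s_Gmax[s] * a;
      }
      Isyn[s_post[s]] += g * (s_Es[s] - U[s_post[s]]);
    }

    for (int i = 0; i < n; ++i) {
      dU[i] = (-Gmem[i] * U[i] + Isyn[i] + Iapp[i] + Ibias[i]) / Cmem[i];
      dth[i] = n_spiking[i]
        ? (-th[i] + theta0[i] + m[i] * U[i]) / tau_theta[i] : 0.0;
    }
    for (int i = 0; i < n; ++i) {
      U[i] += dt * dU[i];
      th[i] += dt * dth[i];
    }

    for (int s = 0; s < ns; ++s) Gs[s] *= decay[s];

    const double t_next = t_start + (k + 1) * dt;
    for (int i = 0; i < n; ++i) {
      if (n_spiking[i] && U[i] >= th[i]) {
        spikes[i].push_back(t_next);
        spike_theta[i].push_back(th[i]);
        U[i] = (reset_noise_sd > 0.0) ? R::rnorm(0.0, reset_noise_sd) : 0.0;
        for (size_t j = 0; j < outgoing[i].size(); ++j) {
          const int s = outgoing[i][j];
          Gs[s] = s_Gmax[s];
        }
      }
      if (std::fabs(U[i]) > guard)
        stop("numerical instability: |U| exceeded %g mV at t = %g ms "
             "(neuron %d); reduce dt", guard, t_next, i + 1);
    }

    if ((k + 1) % record_every == 0 && isamp < nsamp) {
      t_out[isamp] = t_next;
      for (int i = 0; i < n; ++i) {
        U_out(isamp, i) = U[i];
        th_out(isamp, i) = th[i];
      }
      if (record_gs) for (int s = 0; s < ns; ++s) Gs_out(isamp, s) = Gs[s];
      ++isamp;
    }
  }

  List spk(n), spk_th(n);
  for (int i = 0; i < n; ++i) {
    spk[i] = NumericVector(spikes[i].begin(), spikes[i].end());
    spk_th[i] = NumericVector(spike_theta[i].begin(), spike_theta[i].end());
  }

  return List::create(
    _["time"] = t_out,
    _["U"] = U_out,
    _["theta"] = th_out,
    _["Gs"] = record_gs ? (SEXP)Gs_out : R_NilValue,
    _["spikes"] = spk,
    _["spike_theta"] = spk_th,
    _["state"] = List::create(
      _["U"] = NumericVector(U.begin(), U.end()),
      _["theta"] = NumericVector(th.begin(), th.end()),
      _["Gs"] = NumericVector(Gs.begin(), Gs.end())),
    _["n_steps"] = (double)nstep);
}
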