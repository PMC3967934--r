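#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// L1 discretization of the Caputo fractional leaky integrate-and-fire model.
//
// Update for the voltage at step N (N >= 2, uniform grid t_k = k*dt):
//
//   V_N = (dt^alpha * Gamma(2 - alpha) / C_m) * (-g_L (V_{N-1} - V_L) + I_N)
//         + V_{N-1} - M_N
//   M_N = sum_{k=0}^{N-2} (V_{k+1} - V_k) * [ (N-k)^{1-alpha} - (N-1-k)^{1-alpha} ]
//
// The most recent increment's unit weight is absorbed into the explicit
// update; the remaining weighted sum over past increments is the
// voltage-memory trace M_N. The first step, where no past increments exist,
// is the single-sample L1 update (forward-Euler at alpha = 1).
//
// Fire-and-reset: the spike sample records V_th, then the voltage is clamped
// to V_reset while the refractory countdown is positive; the neuron is
// eligible to fire again at the first grid point with countdown <= 0. All
// clamped samples enter the history used by the memory sum. With
// reset_memory = true the history is truncated at each spike (the memory sum
// restarts from the first reset sample).
//
// The memory trace and Markov term are recorded at every step (including
// refractory samples) for diagnostics; the memory sum costs O(N) per step,
// O(N^2) total, computed exactly unless trunc_window > 0 limits the lookback.
// alpha == 1 short-circuits to the classical (memoryless) model in O(N).

// [[Rcpp::export(name = ".flif_simulate_cpp")]]
List flif_simulate_cpp(NumericVector current, double dt,
                       double C_m, double g_L, double V_L,
                       double V_reset, double V_0, double V_th,
                       double tau_ref, double alpha,
                       bool reset_memory, int trunc_window) {
  const int n = current.size();
  const bool classical = (alpha == 1.0);
  const double kappa = std::pow(dt, alpha) * std::tgamma(2.0 - alpha);

  NumericVector V(n + 1), mem(n + 1), markov(n + 1);
  std::vector<double> spikes;
  // P[j] = j^(1-alpha); weight of the increment at lag j is P[j] - P[j-1]
  std::vector<double> P;
  if (!classical) {
    P.resize(n + 2);
    for (int j = 0; j <= n + 1; ++j) P[j] = std::pow((double)j, 1.0 - alpha);
  }

  V[0] = V_0;
  mem[0] = NA_REAL;
  markov[0] = NA_REAL;

  int hist_start = 0;          // first index of the active history
  int clamp_left = 0;          // refractory samples still to clamp
  // the spike sample consumes one dt of the refractory clock; the neuron is
  // eligible again at the first grid point at least tau_ref after the spike.
  // At least one reset sample is always recorded so the reset increment
  // enters the history.
  int n_clamp = (int)std::ceil(tau_ref / dt) - 1;
  if (n_clamp < 1) n_clamp = 1;

  for (int N = 1; N <= n; ++N) {
    const double I_now = current[N - 1];
    const double drive = (-g_L * (V[N - 1] - V_L) + I_now) / C_m;

    double M = 0.0, mk;
    bool bootstrap = (N - 1 - hist_start) < 1;  // fewer than 2 history samples
    if (bootstrap) {
      // single-sample L1 step: no past increments yet, so the update is
      // kappa * drive (identical to a forward-Euler step at alpha = 1)
      mk = kappa * drive;
    } else {
      mk = kappa * drive;
      if (!classical) {
        int k0 = hist_start;
        if (trunc_window > 0 && N - trunc_window > k0) k0 = N - trunc_window;
        const double *p = &P[0];
        for (int k = k0; k <= N - 2; ++k) {
          M += (V[k + 1] - V[k]) * (p[N - k] - p[N - 1 - k]);
        }
      }
    }
    mem[N] = bootstrap ? 0.0 : M;
    markov[N] = mk;

    if (clamp_left > 0) {              // clamped: refractory period
      V[N] = V_reset;
      --clamp_left;
      continue;
    }

    double cand = mk + V[N - 1] - M;
    if (!std::isfinite(cand))
      stop("non-finite voltage candidate at step %d (t = %g ms)", N, N * dt);

    if (cand >= V_th) {                // inclusive threshold crossing
      V[N] = V_th;                     // spike sample records the threshold
      spikes.push_back(N * dt);
      clamp_left = n_clamp;
      if (reset_memory) hist_start = N + 1;  // history restarts at the reset
    } else {
      V[N] = cand;
    }
  }

  return List::create(_["voltage"] = V,
                      _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
                      _["memory_trace"] = mem,
                      _["markov_term"] = markov);
}
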