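---
title: "The fractional leaky integrate-and-fire model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fractional leaky integrate-and-fire model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flif)
```

## The model

The classical leaky integrate-and-fire (LIF) neuron is Markovian: the
membrane voltage depends only on its previous value. Real neurons,
however, show multiple-timescale adaptation — power-law sub-threshold
relaxation, inter-spike intervals that keep drifting under constant
drive, firing that depends on stimulation seconds in the past. `flif`
models this by replacing the first-order time derivative of the membrane
equation with a Caputo fractional derivative of order $\alpha \in (0,1]$:

$$C_m \, \frac{d^\alpha V}{dt^\alpha} = -g_L\,(V - V_L) + I(t),$$

with the usual fire-and-reset rule: when $V$ reaches $V_{th}$ a spike is
recorded, the spike sample is clipped at $V_{th}$, and the voltage is
clamped at $V_{reset}$ for a refractory period $\tau_{ref}$. At
$\alpha = 1$ the model is exactly the classical LIF; as $\alpha$
decreases the voltage becomes increasingly correlated with its own past.

The Caputo derivative is discretized with the L1 finite-difference
scheme on a uniform grid $t_k = k\,\Delta t$. Solving the discretized
equation for the newest sample gives an explicit update,

$$V_N = \underbrace{\frac{\Delta t^\alpha\,\Gamma(2-\alpha)}{C_m}
\left[-g_L (V_{N-1} - V_L) + I\right]}_{\text{Markov term}}
 + V_{N-1} -
\underbrace{\sum_{k=0}^{N-2} \left(V_{k+1}-V_k\right)
\left[(N-k)^{1-\alpha} - (N-1-k)^{1-\alpha}\right]}_{\text{voltage-memory trace}},$$

implemented in `flif_simulate()` (compiled core) and mirrored by the
readable R stepper `flif_advance()`; the two are cross-checked in the
test suite. The power-law weights (`memory_weights()`) are zero at
$\alpha = 1$, positive and heavy-tailed otherwise, and grow pointwise as
$\alpha$ decreases; the Markov prefactor
$\Delta t^\alpha \Gamma(2-\alpha)$ (`gamma_coefficient()`) grows too.
Their competition is the whole story of the model: the memory trace has
the sign of the recent voltage trajectory and is subtracted, so a
depolarizing past *opposes* further depolarization (adaptation, pauses,
long first-spike latencies), while a reset leaves a transient negative
(accelerating) contribution.

Everything is kept in a self-consistent unit system of mV, ms, nA, nF
and µS (nF·mV/ms = nA); the 25 nS leak of the standard set is stored as
0.025 µS. The dimensional subtlety of a capacitance multiplying a
ms$^{-\alpha}$ derivative is handled purely numerically in these fixed
units, exactly as the discretized update prescribes — no attempt is made
to rescale $C_m$ into fractional units.

### Parameters

`flif_params()` provides the standard set (`preset = "table1"`):
$C_m = 0.5$ nF, $g_L = 0.025$ µS ($\tau_m = 20$ ms),
$V_L = V_{reset} = V_0 = -70$ mV, $V_{th} = -50$ mV,
$\tau_{ref} = 5$ ms, injected currents of order 3 nA
(threshold current $g_L (V_{th}-V_L) = 0.5$ nA). The slower
`preset = "adapted"` ($g_L = 0.005$ µS so $\tau_m = 100$ ms,
$\tau_{ref} = 10$ ms) is used for the oscillatory-drive,
history-dependence and noise protocols, where a slower membrane matches
cortical recordings; the exact values behind this preset are a package
choice, made once, since the source tables for the slow variant are not
machine-readable. $\tau_m$ is always derived as $C_m/g_L$, never stored.

The biophysically interesting regime is $\alpha \lesssim 0.2$: only
there does the memory trace overcome the Markov term. Note that the
*effective* rheobase rises sharply as $\alpha$ falls — at
$\alpha = 0.1$ under the adapted preset the model needs roughly 5 nA of
constant drive to sustain firing even though the nominal threshold
current is 0.1 nA. Protocol defaults take this into account.

### Numerical choices

* **Time step.** `dt = 0.1` ms is the reference step; the spiking
  protocol studies use 0.5 ms, chosen so that the full test suite and
  the reproduction script run in minutes. Convergence (not a fixed
  step) is what the tests assert: the sub-threshold trace converges
  monotonically to the closed-form Mittag-Leffler solution as `dt`
  halves from 1 to 0.125 ms, for $\alpha \in \{0.3, 0.5, 0.8\}$.
* **First step.** The update needs two samples, so the very first step
  is the single-sample L1 step
  $V_1 = V_0 + \Delta t^\alpha\,\Gamma(2-\alpha)\,\text{drive}$ —
  the L1 scheme's own $N{=}1$ case, which reduces to a forward-Euler
  step at $\alpha = 1$. An Euler first step was tried and rejected: its
  linear first-sample rise crosses the true $t^\alpha$ rise near
  $\Delta t \approx 1$ ms, which makes coarse grids accidentally
  accurate and destroys the monotone-convergence property above.
* **Threshold and refractory conventions.** Threshold crossing is
  inclusive ($V \ge V_{th}$); the spike sample records $V_{th}$; the
  neuron becomes eligible to fire again at the first grid point at
  least $\tau_{ref}$ after the spike, and at least one reset sample is
  always recorded so the reset increment enters the memory sum. All
  clamped samples stay in the history — this is required to reproduce
  the negative post-reset memory transient and the accumulation of
  adaptation across spikes.
* **Complexity.** The memory sum is exact (no truncation): $O(N)$ per
  step, $O(N^2)$ per run, with a precomputed $j^{1-\alpha}$ table. A
  truncation window exists (`trunc_window`) but is off by default
  because the multi-second recovery effects live in the full trace.
  $\alpha = 1$ short-circuits to the $O(N)$ classical model.
* **Memory reset.** `memory_mode = "reset_on_spike"` truncates the
  history at each spike. Under constant current this variant fires
  regularly after the first spike and matches the closed-form
  memory-reset reference (`simulate_analytic_reset()`) to within one
  time step.

## The Mittag-Leffler reference solution

For constant sub-threshold current the model has the closed form

$$V(t) = V_\infty + (V_0 - V_\infty)\,
E_\alpha\!\left(-\,t^\alpha/\tau_m\right),
\qquad V_\infty = V_L + I/g_L,$$

where $E_\alpha$ is the one-parameter Mittag-Leffler function. This is
both a model variant in its own right (with fire-and-reset and a time
origin restarted at every spike, it is the memory-reset spiking model)
and the independent oracle for the L1 integrator.

`mittag_leffler()` sums the power series for $|z| < 1$. For
$z \le -1$ the alternating series cancels catastrophically (its largest
terms reach $e^{200}$ by $z \approx -5$ at small $\alpha$), so the
completely monotone spectral representation

$$E_\alpha(-x) = \frac{\sin(\alpha\pi)}{\pi\alpha}
\int_0^\infty \frac{e^{-(u x)^{1/\alpha}}}
{u^2 + 2u\cos(\alpha\pi) + 1}\,du$$

is integrated by adaptive quadrature instead. The switch-over sits at
$|z| = 1$, well inside the series' safe region; both branches are
validated in the tests against frozen 30-digit arbitrary-precision
values and against the identity
$E_{1/2}(-x) = e^{x^2}\,\mathrm{erfc}(x)$.

`time_to_fire()` inverts the closed form by root-finding
(`method = "exact"`, the default, used everywhere results matter) or
evaluates the small-time truncation
$E_\alpha(-t^\alpha/\tau_m) \approx 1 - t^\alpha/(\tau_m\Gamma(1+\alpha))$
in closed form (`method = "smalltime"`); the truncation is kept because
it underlies the classical firing-rate approximation, but it is accurate
only for $t \lesssim 0.1\,\tau_m$ and the two methods genuinely disagree
at $\alpha = 1$ (3.65 vs 3.33 ms for the standard 3 nA drive) — the
exact method is the one that matches the classical limit.

## Stimulus generators

All protocols are declarative (`stim_step()`, `stim_pre_post()`,
`stim_sine()`, `stim_square()`, `stim_zap()`, `stim_noisy()`,
`stim_embedded()`) and rendered by `render_stimulus()` as pure
functions of (spec, grid, seed). Choices worth stating:

* The ZAP chirp's instantaneous frequency follows a logistic sigmoid
  from 0 to 100 Hz over 10 s; the exact steepness is exposed as a
  parameter (at the default the endpoints are reached within 1%; the
  impedance validation uses `steepness = 2` so that stimulus energy
  covers the full 1–100 Hz band). The phase is the running integral of
  the instantaneous frequency, so the waveform has no jumps.
* Noise is generated per-sample at the grid rate (white up to Nyquist),
  scaled per-epoch when a variance schedule is given, then filtered
  with the causal alpha kernel $(t/\tau^2)e^{-t/\tau}$ normalized to
  unit area on the grid.
* Epoch durations that are not multiples of `dt` are rounded down with
  a warning.

## Quantification procedures

* **Instantaneous rate** is the reciprocal ISI placed at the interval
  midpoint; the first-interval rate is exposed separately because the
  conditioning protocols are read from it.
* **Impedance** is the ratio of FFTs of the mean-subtracted voltage and
  current over a spike-free epoch (mV/nA = MΩ), reported over 1–100 Hz
  with a 1 Hz boxcar on the magnitude; phase is negative when voltage
  lags current. At $\alpha = 1$ it matches the analytic RC form within
  2% across the band at `dt = 0.1` ms; at low $\alpha$ the profile
  flattens and the lag shrinks and becomes frequency-insensitive.
* **Gain and phase** at a known period come from a linear least-squares
  sine fit to the rate (offset, sine and cosine amplitudes); the gain
  is rate amplitude over current amplitude, in (spikes/s)/nA — the
  units are a documented package choice. The gain study
  (`protocol_gain_study()`) simulates each period from rest and fits
  the whole trace: the freshly stimulated neuron, its memory building
  during the epoch, is what shows the clean $T^{-\alpha}$ gain law
  (log-log slope $-0.19$ at $\alpha = 0.2$ with the default 2.5 nA
  mean, 0.3 nA amplitude, 3 cycles). Discarding the onset cycles
  biases the slope toward zero (about $-0.13$) because the adapted
  response tracks long periods quasi-statically; both behaviors are
  real, and the protocol documents which one it measures.
* **Adaptation time constants** are single-exponential fits to the
  folded rate (cycles after the first pooled onto one period), with a
  50 ms margin inside each half-period so intervals straddling a level
  transition do not contaminate the fit.
* **ISI histograms** are log-binned (10 bins per decade) and the
  power-law and exponential models are compared by $R^2$ on the same
  occupied-bin support.
* **Reliability** binarizes each train on the grid over the analysis
  epoch, smooths with a Gaussian (default width 3 ms), and averages the
  pairwise normalized inner products. It is permutation-invariant and
  invariant to common time shifts.
* **Recovery metrics**: the five-cycle protocol compares the
  second-to-last ISI of the last versus the first cycle;
  `pause_after_pulse()` measures the silent period after a pulse, with
  a censoring flag when firing never resumes in the simulated span.

## The exponent-fitting module

`fit_alpha()` minimizes the mean squared error between a reference
curve and model curves simulated over an exponent grid (default 0.05 to
1 in 0.01 steps — finer than a 0.1-step exploratory grid, because the
interesting exponents sit below 0.5; the coarse grid is available as
`alpha_grid_coarse()`). The 95% confidence interval follows the
5%-change rule: walking away from the minimum, the interval covers all
grid exponents whose MSE stays within 5% of the minimum. The rule is
interpreted as *relative* change (the natural reading for an MSE whose
scale depends on the metric) and the fraction is configurable.
`fit_alpha_isi()` adds the step-current ISI-curve metric with an
optional leading-ISI truncation mirroring fits that drop the initial
transient.

## The synthetic-data generator

`generate_fixtures()` synthesizes every reference curve the tests need,
from the model itself at known exponents: ISI-versus-index curves at
$\alpha \in \{0.15, 0.2, 0.4\}$ (noiseless and with 5% multiplicative
noise), a rate-versus-time curve under a 16 s square-wave drive, and
raster ensembles for reliability, each with a JSON sidecar holding the
generating parameters. These fixtures emulate the *shape* of digitized
experimental curves (a decaying ISI sequence, an adapting rate, a
raster) but none of the biological nuisance structure — electrode
noise, nonstationarity, spike-sorting errors, cell-to-cell variability.
Passing the closed-loop recovery tests therefore shows that the fitting
machinery is correct and well-conditioned, not that the model fits any
particular real neuron.

## Study protocols and their chosen conditions

Where the protocol conditions are not fixed by printed values, the
package fixes them once, as follows, and the reproduction script and
tests use exactly these:

* **Five-cycle gap protocol** (`protocol_five_cycles()`): five 1 s
  steps of 4 nA at $\alpha = 0.2$, adapted preset, gaps swept 0.25–6 s
  at `dt = 0.5` ms. With these conditions the second-to-last-ISI ratio
  re-enters the 5% band around a 6 s gap, and the first ISI of Cycle 5
  still differs from Cycle 1 by more than one time step at every gap up
  to 25 s — the long-memory bound. The absolute re-entry gap is
  sensitive to the cycle duration and membrane preset; the qualitative
  structure (fast second-to-last-ISI recovery, first-ISI recovery
  beyond 25 s) is not.
* **Pause protocol** (`protocol_pause()`): $\alpha = 0.1$, adapted
  preset, baseline 5 nA (the smallest half-nanoamp step that sustains
  tonic firing at this exponent), 1 s pulses of 1–9 nA on top. The
  pause grows with pulse amplitude and saturates once the in-pulse rate
  hits the refractory ceiling ($1000/\tau_{ref} = 100$ spikes/s),
  at about 370 ms under these conditions; the saturated value scales
  steeply with the baseline's margin above the effective rheobase and
  with the pulse duration.
* **Reliability study** (`protocol_reliability_study()`): for each
  $\alpha \in \{1, 0.6, 0.2\}$ the mean current is calibrated by
  bisection to 14 spikes/s, then 20 trials of 10 s receive independent
  alpha-filtered Gaussian noise ($\sigma = 0.03$ nA per sample,
  $\tau = 2$ ms) and the last 5 s are analyzed. The weak noise is the
  point: it perturbs spike-time phase without taking over the drive,
  and the fractional memory's resistance to phase diffusion is what
  raises R from 0.14 ($\alpha = 1$) to 0.40 ($\alpha = 0.2$).

## Problem sizes

The test-suite simulations use 0.5 ms steps for spiking protocols
(0.1–0.025 ms where sub-threshold accuracy is asserted), spans of 1–64 s,
20-trial ensembles, and 20 fit replicates; the exact memory sum makes a
run of $N$ steps cost $O(N^2)$, which keeps the longest single runs
(the 25 s-gap five-cycle protocol, ~2·10⁵ steps) around twenty seconds.
These sizes were chosen so the whole suite completes in a few minutes
while every assertion retains a comfortable margin; all of them are
arguments, and larger spans or finer steps reproduce the same
qualitative results.

## Known limitations

* No action-potential waveform, conductance-based adaptation currents,
  synaptic input, or cable/multi-compartment structure: current
  injection into a point membrane only.
* The O(N²) exact memory sum makes multi-minute simulations at 0.1 ms
  steps expensive; the truncation window trades long-memory fidelity
  for speed and is therefore off by default.
* The Mittag-Leffler evaluator covers real arguments (negative is the
  use case); no complex arguments.
* Printed recovery and pause magnitudes depend on protocol constants
  (cycle duration, baseline margin, pulse length) that are package
  choices where no printed value exists; the package reproduces the
  phenomena and their orderings robustly, but those two absolute
  numbers should be read together with the protocol definition above.
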