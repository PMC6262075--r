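---
title: "Modelling bistable molecular-switch dynamics with switchdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bistable molecular-switch dynamics with switchdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchdyn)
```

## The model

`switchdyn` simulates and analyses a reduced model of a bistable molecular
switch, written with CaMKII (calcium/calmodulin-dependent protein kinase II)
in mind but applicable to any kinase stabilized by phosphatase activity and
self-excited through cooperative autophosphorylation. The state variable
$x \ge 0$ is the dimensionless concentration of activated switch and obeys

$$ T\,\frac{dx}{dt} \;=\; c(t) \;-\; r\,x \;+\; \frac{x^n}{1 + x^n}, $$

where $c(t) = c_0 + c_l(t) \ge 0$ is the calcium drive (a residual baseline
$c_0$ plus fast local transients), $r$ is the strength of negative
regulation by phosphatases, $n$ is the Hill exponent of cooperative
autophosphorylation, and $T$ (seconds) is the timescale factor — the ratio
of the dissociation and association constants of the underlying kinetics.
The four-constant dimensional kinetics
$dy/dt = k_0 s - k_1 y + k_2 y^n/(k_3^n + y^n)$ reduce to this form under
$y = x k_3$, with $r = k_1 k_3 / k_2$, $T = k_3/k_2$ and the input map
$c = (k_0/k_2)\,s$; `nondimensionalize()` performs the reduction and its
correctness is checked by a dual-simulation test that integrates both forms
against mapped inputs. (The direction of the input map is fixed by the
algebra of the substitution; the dual-simulation test pins it down
unambiguously.)

Setting `hill = FALSE` in `switch_params()` removes the activation term,
modelling a T286A-like mutant that cannot autophosphorylate; the dynamics
then become the linear relaxation $T\,dx/dt = c - r x$, which has a closed
form used throughout the tests as an exact oracle.

### Defaults and units

All times are seconds, rates in Hz. Default parameter choices:

* `T = 0.01` s — the kinase's dissociation constant is at least two orders
  of magnitude below its association constant, and this value supports
  reliable tracking of 1–15 Hz input. The long-timescale protocols use
  `T = 0.4` and `T = 0.1` respectively: slow autonomous-activation readouts
  operate in a different effective regime, and both values are first-class
  arguments rather than a reconciled single constant.
* `n = 2` for the analytical work (closed forms exist), `n = 1.6` for the
  physiologically motivated simulations (the empirical Hill exponent of
  presynaptic alpha-CaMKII).
* `c0 = 0.04` — a residual calcium drive inside the hysteresis-supporting
  range for the bistable parameter sets used here.
* `dt = 0.001` s everywhere.

## Equilibria, bifurcation and hysteresis

For constant drive the fixed points solve $c - rx + x^n/(1+x^n) = 0$; for
$n = 2$ this is the cubic $-rx^3 + (c+1)x^2 - rx + c = 0$, solved in closed
form and polished by Newton steps (`fixed_points()`); for general $n$ the
sign changes of the drift are bracketed on $[0,(c+1)/r + 1]$ — beyond that
point the drift is negative — and refined by bisection to $10^{-12}$.
Stability is the sign of $f'(x^*)$; the measure-zero tie $f'(x^*) = 0$ is
labelled unstable and flagged `saddle_node` so sweeps cannot silently sit
on a fold.

Saddle-node boundaries are parametrized by the fold location:
$r_c(x) = n x^{n-1}/(1+x^n)^2$ and $c_c(x) = r_c(x)\,x - x^n/(1+x^n)$
(`critical_curves()`). For $n = 2$, $r_c(1) = 1/2$, the largest drive
supporting bistability is $c_c = 1/8$, and the two branches meet
tangentially at the codimension-two point $(c, r) = (1/8,\, 3\sqrt3/8)$.
The same tangency conditions define the curves for general $n$ — a direct
extension of the $n = 2$ analysis. `hysteresis_sweep()` follows the
occupied stable branch along a drive path in the adiabatic limit (occupy
the nearest stable fixed point; jump only when the branch disappears), so
up- and down-jumps land at the two folds of the slice.

## Stimulus generators

* `poisson_pulse_train()` — homogeneous Poisson pulse times; seeded and
  reproducible, with the global RNG state untouched (`withr`).
* `pulses_to_calcium()` — causal alpha-function kernel
  $(t - t_i)\,e^{-(t - t_i)/\tau_c}$ with $\tau_c = 30$ ms by default,
  matching the time course of local synaptic calcium transients. The summed
  response is normalized to its realized maximum and scaled by `delta_c`,
  so the peak of $c$ is exactly $c_0 + \Delta c$ for any non-empty train.
  A literal non-causal reading of a "t times exponential" filter is
  rejected by construction: the kernel is zero before its pulse, and a
  causality unit test asserts that later pulses cannot alter earlier
  samples.
* `sinusoidal_input()` — $c_0 + \alpha \sin(2\pi\varphi t)$, warning when
  $\alpha > c_0$ (the drive would dip below zero; integrators floor the
  total drive at zero regardless, and the flooring rate is recorded on
  noisy trajectories).
* `exp_decay_calcium()` — linear superposition of first-order decays
  (200 ms default), the shape measured for dendritic calcium under
  repetitive stimulation. No normalization here: each pulse adds exactly
  `delta_c`.

## Noise model and discretization

Drive noise is an Ornstein–Uhlenbeck process entering additively through
$c$ ("weak noise in the calcium amplitude"). We write the OU equation in
units of its own correlation time and apply the stochastic Euler
(Euler–Maruyama) scheme on the simulation grid:

$$ \eta_{k+1} = \eta_k - \frac{\eta_k}{\tau_\eta}\,dt
   + \sigma\sqrt{dt/\tau_\eta}\;\xi_k, \qquad \xi_k \sim N(0,1)
   \text{ bounded at } \pm 5 \text{ SD}. $$

Under this normalization $\sigma$ is an amplitude in drive units: the
stationary variance is $\sigma^2/2$ *independent of the step size*, while
the autocorrelation time remains $\tau_\eta$ (10 ms by default, the upper
bound for noisy microdomain calcium). The alternative convention that
scales increments by $\sqrt{dt}$ alone makes the stationary amplitude
depend on $\tau_\eta$ and, for the noise ranges of interest here
($\sigma \le 1$), produces fluctuations far too weak to gate transitions
between activation states — no stochastic-resonance maximum exists
anywhere on the sweep grid. The amplitude-normalized convention reproduces
the full resonance phenomenology (see below) and is therefore the
package's definition of $\sigma$. The driving deviates are clipped at
$\pm 5$ SD (configurable), preserving the boundedness needed by the
trapping argument at a negligible distributional cost (clip probability
$\approx 6\times10^{-7}$).

## Integration

`simulate_switch()` runs classical RK4 on $dx/dt = f/T$ over the signal's
uniform grid. Two numerical choices matter:

* **Half-step forcing.** The drive is interpolated at RK4 half-steps with a
  4-point cubic (linear at the grid ends). Linear midpoint interpolation
  caps the global order at two for time-varying drives; the cubic restores
  genuine 4th-order behaviour, verified by a Richardson test whose error
  ratio under step halving is ≈ 16.
* **Noise splitting.** Within a step the OU sample $\eta_k$ is held
  constant and added to the drive (RK4 for the flow, stochastic Euler for
  the noise). This is the simplest splitting consistent with a 1 ms step;
  it is not a higher-order SDE scheme, and none is attempted.

The state is floored at zero after each stage and step: the origin is
repelling whenever $c \ge 0$, so the floor only guards round-off.
The total drive $c + \eta$ is floored at zero before entering the drift
(physiological constraint), and noisy trajectories record the fraction of
floored samples. Default initial condition is the low stable state at
$c = c_0$, recorded in the trajectory's attributes.

## Uniqueness diagnostics

For two solutions $u, x$ sharing the same drive, the gap obeys a Grönwall
bound with rate $(r - \max p)/T$, where
$p(u,x,n) = (u^n - x^n)/\big((u-x)(1+u^n)(1+x^n)\big)$ and the maximum is
attained on the diagonal $u = x$, where $p$ equals the derivative of the
Hill term, $n x^{n-1}/(1+x^n)^2$ (`p_uniqueness()`, `max_p()`). For
$n = 2$ the maximum is $3\sqrt3/8 \approx 0.6495$: negative regulation
above this value forces all initial conditions onto a unique input-driven
response. The diagonal property is not assumed blindly — a 2-D grid oracle
confirms it in the tests for several exponents.

Minimizing $\max_x n x^{n-1}/(1+x^n)^2$ over the exponent
(`argmin_max_p()`) uses a 200-point bracketing grid plus golden-section
refinement to $10^{-4}$. The continuous minimizer is $n^\* = 1.5434$,
reported as 1.54 at two decimals; a coarse grid of step 0.05 rounds the
same minimum to 1.55, which is the conventionally quoted value — the
difference is pure grid resolution, and the acceptance check therefore
accepts agreement within one unit of the second decimal. The expression is
unbounded as $x \to 0^+$ for $n < 1$ (reported as a flagged boundary
supremum), so the minimization effectively runs above $n = 1$ and highly
uncooperative exponents are excluded automatically.

## Stochastic resonance

`sr_sweep()` drives the switch with a weak sinusoid
($c_0 = 0.04$, $\alpha = 0.02$, $\varphi = 2$ Hz — a hippocampal mean
firing rate) plus OU noise, and measures frequency transfer as the ratio
of Hann-window periodogram power of $x$ to that of the noiseless drive at
the bin nearest $\varphi$ (an identity system gives gain 1 to $10^{-10}$,
which the tests assert). The sweep uses 30 log-spaced $\sigma$ values in
$[0.005, 1]$ and, by default, 10 trials of 200 s per value; the acceptance
runs use 20 trials. Sampling design: **common random numbers** — each
trial's noise seed is reused across the whole $\sigma$ grid, so the OU
path scales linearly with $\sigma$ within a trial. Per-$\sigma$ means are
unchanged, but gain fluctuations become strongly correlated between
neighbouring grid points, which stabilizes the argmax $\sigma_p$ on the
flat resonance ridge; a bootstrap over trials supplies an interval for
$\sigma_p$. With the $n = 2$ switch at $r = 0.65$ the gain dips slightly,
rises sharply to an interior maximum, then collapses as noise dominates;
the $n = 1.6$ switch at $r = 0.61$ peaks at a several-fold lower noise
amplitude with a substantially larger peak gain. `sr_map()` repeats the
sweep over $(n, r)$ or $(c_0, r)$ grids and flags cells whose gain curve
has no interior maximum ("no SR").

`activation_histogram()` bins post-burn-in activation with
Freedman–Diaconis widths and reports modality as the number of prominent
modes: local maxima of 5-bin-smoothed counts, discarding peaks below 5% of
the tallest and merging neighbours whose connecting valley exceeds 0.8 of
the smaller peak. Long records make raw local-maxima counts hypersensitive
to bin noise; the prominence rule is the minimal robust alternative, and
at low noise the sinusoid's arcsine-shaped occupancy is correctly read as
bimodal while stronger noise blurs it to unimodal.

## Pulse-train protocols

* **Paired-arm discrepancy** (`discrepancy_experiment()`): two switches
  share identical 8 Hz Poisson calcium trains and differ only in baseline
  ($c_0 = 0.02$, monostable, vs $0.04$, which input traps in the high
  state through hysteresis). Per shared inter-pulse interval the rise
  $\Delta = \max_{(t_i, t_{i+1}]} x - x(t_i)$ is computed in both arms and
  the grand mean of $|\Delta_u - \Delta_x|$ is reported per $r$. The
  statistic is dominated by state-transition intervals and is sensitive to
  the timescale factor; `T` is therefore an explicit argument. Trains are
  shared across the $r$ grid as well, which removes train-to-train
  variance from the profile (the tests verify that paired trains have
  lower variance than independent ones).
* **Burst detection** (`burst_detection_protocol()`): at $r = 0.54$ (below
  the critical $3\sqrt3/8$) with a step schedule on $c_0$, each time step
  is labelled low/high relative to the separatrix, the unstable fixed
  point at the instantaneous baseline; during monostable excursions the
  most recent bistable separatrix is retained. The default pulse amplitude
  `delta_c = 0.12` is calibrated so that the peak drive exceeds the upper
  fold yet a single 30 ms transient cannot transit the fold bottleneck:
  one pulse fails to cross, a 10 Hz pair crosses and hysteresis holds the
  up state. (A static inequality guaranteeing single-pulse safety is
  unsatisfiable under per-realization normalization, since one pulse and a
  pair reach the same normalized peak; the calibration is therefore
  dynamic, through the fold transit time.)
* **Frequency/duration decoding** (`dekoninck_protocol()`): periodic
  square calcium pulses over a frequency × duration grid (defaults
  0.5/1/2/4 Hz × 50/100/200 ms, 30 pulses, amplitude 0.5 from baseline 0,
  all combinations respecting pulse non-overlap), with the long-timescale
  readout $X = \omega \langle x \rangle$ (`autonomous_activation()`,
  trapezoidal average over the stimulus; $\omega = 1$ by default so
  results are reported relative to the maximum cell and the unknown
  proportionality drops out). $X$ grows along both axes and distinct cells
  can decode to the same value — the classic input ambiguity of
  long-timescale integration.
* **Wild type vs mutant** (`chang_protocol()`): thirty 1 Hz
  exponential-decay transients drive the full switch and its
  `hill = FALSE` mutant on the identical input ($n = 1.6$, $T = 0.1$);
  the regulation rate ramps linearly 0.58 → 0.67 over the stimulus
  (constant afterwards), reproducing the slow plateau decay that a fixed
  rate cannot, and both trajectories continue past the stimulus to show
  decay toward baseline. Calcium amplitude and baseline are exposed as
  arguments (`delta_c = 0.5`, `c0 = 0`); the protocol's claims are
  ordinal (wild type ≫ mutant, ramp ⇒ decaying plateau), not absolute.

## Reproducibility plumbing

`validate_config()` completes a configuration with every default recorded
explicitly, rejects unknown keys and invalid ranges, and guards the noise
discretization ($dt < \tau_\eta$). `run_config()` executes a validated
configuration (trajectory, SR sweep, discrepancy sweep, or either
protocol), optionally writing CSV results plus a JSON manifest with the
full configuration, seed, package version and output checksums; re-running
a configuration with the same seed reproduces outputs byte-for-byte.
`preset_config()` names the package's reference set-ups. Every stochastic
component takes an explicit seed; experiment drivers derive per-trial
seeds deterministically from one master seed, so paired designs can share
the pulse-train stream while noise streams differ.

## What the synthetic inputs do and do not emulate

The generators produce idealized calcium proxies: Poisson or periodic
pulse times, stereotyped kernels, stationary OU noise. They do not model
calcium buffering or diffusion, channel-level stochasticity,
activity-dependent pulse-size adaptation, or multi-subunit holoenzyme
structure (no dodecamer states, no subunit exchange, constant rather than
state-dependent $\omega$). Passing tests therefore demonstrate the
dynamical phenomena of the reduced model under controlled forcing — not
quantitative agreement with any particular experimental recording.

## Problem sizes

The test suite and the acceptance script run the stochastic-resonance
sweeps at 30 $\sigma$ values × 20 trials × 200 s (1 ms steps) and the
discrepancy experiment at 10 paired trials × 100 s; analytic quantities
use the optimizer/grid settings described above. These sizes give argmax
and mean estimates whose run-to-run variation is well inside the
comparison tolerances, as checked across several master seeds.

## Known limitations

* The adiabatic hysteresis sweep is a quasi-static idealization; finite
  drive rates shift apparent jump points.
* Spectral gain uses a plain Hann periodogram at one bin; no multitaper or
  Welch averaging (trial averaging plays that role).
* `sigma_p` is a grid argmax; its resolution is the grid spacing
  (log-factor ≈ 1.2 on the default grid).
* The separatrix-based state labels retain the last bistable separatrix
  through monostable episodes — a convention, adequate for the burst
  protocol, not a general basin computation.
* Modality counting is a peak heuristic, not a statistical test of
  multimodality.
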