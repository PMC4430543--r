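---
title: "Capacitive memory in conductance-based neurons: models and numerics"
author: "fracHH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capacitive memory in conductance-based neurons: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracHH)
```

## The model

Dielectric measurements on cell membranes are often better described by a
*constant-phase element* than by an ideal capacitor: the capacitive current is
proportional to a fractional derivative of the voltage,
$I_c = C_m^\alpha\, d^\alpha V_m/dt^\alpha$ with $0 < \alpha \le 1$.  Carrying
this non-ideal capacitor into the Hodgkin-Huxley framework gives the
fractional-order membrane equation

$$C_m^\alpha \frac{d^\alpha v}{dt^\alpha} =
  I(t) - g_{Na} m^3 h\,(v - E_{Na}) - g_K n^4 (v - E_K) - g_L (v - E_L),$$

with $v = V_m - V_{rest}$ (depolarization positive) and the gates $m,h,n$
kept strictly first order: channel gating is assumed Markovian, and giving the
gates the same fractional order as the voltage would conflate two physically
distinct memory sources.  For $\alpha = 1$ the model is exactly the classical
squid-axon model; for $\alpha < 1$ the voltage carries a power-law-weighted
memory of its entire history ("capacitive memory").

Standard parameters (rest-relative convention): $g_{Na} = 120$, $g_K = 36$,
$g_L = 0.3$ mS/cm², $E_{Na} = 115$, $E_K = -12$, $E_L = 10.6$ mV.
$C_m^\alpha$ is numerically 1 in µF/cm²-based units, with the residual
$\mathrm{ms}^{\alpha-1}$ factor absorbed into the units, so that $\alpha = 1$
recovers the classical model without rescaling anything.

The same membrane is embedded at three scales:

* **patch** — space-clamped single compartment (`simulate_patch()`);
* **cable** — a 1-cm axon, method of lines at $\Delta x = 0.5$ mm with sealed
  (zero-flux) ends and a voltage-diffusion current
  $g\,(v_{i+1} - 2v_i + v_{i-1})/\Delta x^2$ (`simulate_cable()`);
* **network** — $N = 50$ neurons with random connectivity and instantaneous
  sigmoidal synapses (`simulate_network()`).

## The Grunwald-Letnikov scheme

Because the model starts at rest ($v(0) = 0$), the Riemann-Liouville, Caputo,
and Grunwald-Letnikov definitions of $d^\alpha/dt^\alpha$ coincide, and the
explicit GL discretization applies:

$$v_{n+1} = \sum_{k=1}^{n+1} c_k^\alpha\, v_{n+1-k} + (\Delta t)^\alpha
  f(t_n, v_n, m_n, h_n, n_n), \qquad
  c_1^\alpha = \alpha,\quad c_k^\alpha = \Bigl(1 - \tfrac{1+\alpha}{k}\Bigr) c_{k-1}^\alpha.$$

Gates advance by forward Euler; at $\alpha = 1$ the weight table collapses to
$(1, 0, 0, \dots)$ and the whole scheme *is* forward Euler.  The weights are
generated once per $(\alpha, n)$ by the recursion (the closed-form binomial
expression overflows the gamma function for large $k$ and is used only as a
test oracle) and they sum to 1, decaying as
$c_k \sim \alpha\,k^{-(1+\alpha)}/\Gamma(1-\alpha)$.

The *voltage memory trace*
$v_{mem}(t_{n+1}) = \sum_{k=1}^{n} c_{k+1}^\alpha v(t_{n-k})$ (first two
samples defined as 0) isolates the influence of the non-immediate history and
is recorded alongside each trajectory.

### Memory policies

The history sum is the whole cost of the method: evaluated naively it is
$O(N^2)$ in the number of steps.  Three policies are provided
(`solver_config(memory = ...)`):

* **full** — exact dot product over the stored history.  Default for runs of
  up to $10^5$ steps.
* **truncated(L)** — short-memory: keep the most recent $L$ terms.  The error
  is bounded by the dropped tail mass $\sum_{k>L} c_k^\alpha$
  (`gl_tail_mass()`) times $\max |v|$; this genuinely changes the result and
  is off by default.
* **compressed(K0)** — exact weights for the most recent $K_0$ steps
  (default 1024) plus the tail carried as recursively updated exponential
  moments.  This exploits the complete-monotone integral representation
  $c_k^\alpha = \frac{\sin \pi\alpha}{\pi}\int_0^\infty e^{-ks}\,
  e^{\alpha s}(1 - e^{-s})^\alpha\, ds$: discretizing the integral with
  Gauss-Legendre panels on a geometric grid gives
  $c_k \approx \sum_m w_m \rho_m^k$ with relative weight error around
  $10^{-9}$ for $\alpha \le 0.6$ (checked at construction and reported), so
  the policy evaluates the *same* full-history sum at $O(K_0 + M)$ cost per
  step.  Unlike truncation this is an evaluation strategy, not a model
  change; the test suite verifies full and compressed trajectories agree to
  about $10^{-5}$ mV on spiking runs.

The `"auto"` default uses full history up to $10^5$ steps and compressed
beyond, which keeps the longest runs in this package (network simulations at
$\alpha = 0.4$) tractable on one CPU.

### Time steps and stability

The explicit scheme's effective gain scales with $(\Delta t)^\alpha$, so
smaller orders need smaller steps.  Package defaults (`default_dt()`):
$10^{-3}$ ms for $\alpha \ge 0.8$, $5 \times 10^{-4}$ ms for
$0.5 \le \alpha < 0.8$, $10^{-4}$ ms below.  These are validated by the
first-order convergence test (halving $\Delta t$ roughly halves the terminal
error of the passive-membrane benchmark).  Gates are clamped to
$[0,1]$ after each Euler step: they are probabilities, and the clamp keeps
the explicit update bounded under extreme hyperpolarization, where the
closing rates grow exponentially with $|v|$ and would otherwise make the
gate update stiffly unstable (the clamp never engages in ordinary spiking
regimes).  Any trajectory reaching
$|v| > 1000$ mV or a non-finite value aborts with the failing step and a
suggestion to reduce $\Delta t$.  For the cable an additional heuristic warns
when $g\,\Delta t^\alpha / \Delta x^2$ exceeds 0.5.

## Analytic passive-membrane theory

The passive membrane ($R_m C_m^\alpha$ circuit) admits closed forms used both
as science and as oracles for the integrator:

* step response $V_m(t) = R_m I_m [1 - E_{\alpha,1}(-(t/\tau)^\alpha)]$
  (`step_response()`), with $\tau^\alpha = R_m C_m^\alpha$;
* strength-duration curve
  $I_t = I_{rheo}/[1 - E_{\alpha,1}(-(d/\tau)^\alpha)]$
  (`strength_duration()`), which follows the empirical power law
  $d^{-\alpha}$ at short durations;
* impedance $Z = R_m/(1 + R_m (j\omega C_m)^\alpha)$ (`impedance()`), whose
  high-frequency phase is $-90\alpha$ degrees.  At a normalized frequency of
  $10^3$ the phase of the $\alpha = 0.5$ membrane is still 1.25° away from
  its asymptote; the asymptotic statement holds to within 1° from about
  $\omega\tau = 10^4$, which is where the package's asymptotic checks are
  evaluated.

`mittag_leffler()` evaluates $E_{\alpha,\beta}(z)$ by the defining series for
moderate arguments, a Hankel-contour integral collapsed onto the negative real
axis for large negative arguments (with the residue-type term $-1/z$ when
$\beta = \alpha + 1$), and the asymptotic series beyond; the chain is verified
against 40-digit arbitrary-precision sums and against
$E_{1/2,1}(-x) = e^{x^2}\mathrm{erfc}(x)$.

### Passive cable

In normalized units ($x$ in $\lambda = \sqrt{R_m g}$, $t$ in $\tau$) the
fractional cable equation Fourier-transforms, per wavenumber, into a linear
fractional relaxation solved exactly by Mittag-Leffler functions; the package
inverts the spatial transform by quadrature (`cable_green()`,
`cable_step_response()`).  Two independent checks pin this down: the
$\alpha = 1$ kernel matches $e^{-t - x^2/4t}/\sqrt{4\pi t}$ to $10^{-4}$, and
the fractional step response matches a Talbot inversion of the exact
Laplace-domain solution $e^{-|x|\sqrt{1+s^\alpha}}/(2s\sqrt{1+s^\alpha})$ to
five digits.

**Pseudo-velocity fit range.**  The sub-threshold "pseudo-velocity" is the
slope of the locus where $V(x,t)/V_{ss}(x)$ first reaches $1/2$.  This slope
is *not* range-independent for $\alpha < 1$: the sub-diffusive response
spreads faster than the classical one near the source but its front position
grows sublinearly in time, so beyond roughly one space constant the ordering
reverses.  The package fits over $x \in [0.05\lambda, 0.25\lambda]$, the
near-field window in which the two canonical facts hold simultaneously —
the $\alpha = 1$ slope is $\approx 2\,\lambda/\tau$ (1.92 measured) and the
slope increases monotonically as $\alpha$ decreases (1.92 / 1.96 / 2.09 /
2.68 for $\alpha$ = 1 / 0.8 / 0.6 / 0.4).  A far-field window such as
$[0.5\lambda, 2\lambda]$ would reverse the trend; users probing the far field
can pass their own `x_fit`.

## Active cable conventions

The axial conductance is quoted in µS (reference values 7.06 and 0.706).  The
discrete coupling current is $g\,(v_{i+1} - 2v_i + v_{i-1})/\Delta x^2$ with
$g$ in µS and $\Delta x$ in cm taken numerically, i.e. an effective coupling
density $g/\Delta x^2 = 2.824$ mS/cm² for $g = 7.06$ µS — the same scale as
the ionic conductances, and the first-order cable then conducts at a
physiological $\approx 0.17$ cm/ms.  The sealed ends use one-sided second
differences, which make the discrete Laplacian conservative (total $\sum_i v_i$
is invariant when all membrane currents are switched off; this is a unit
test).  Propagation velocity is measured from spike peak times at
$x = 0.25$ and $0.75$ cm, with parabolic sub-sample peak interpolation.

## Spike metrics

Figure-level spike measurements in this field rarely define "spike"
operationally, so the package fixes and exposes one criterion: a local maximum above 40 mV
(rest-relative) separated by at least 2 ms from its neighbours.  Thresholds
are located by bisection on a 0.1-ms pulse amplitude to 0.5 µA/cm²; the
refractory interval bisects the two-pulse inter-stimulus interval to 0.05 ms;
repetitive-firing statistics are computed over the final 30 ms of a 100-ms
constant-stimulus run, and both a count-based and a mean-instantaneous
frequency are reported (they differ negligibly for regular trains).  The
spiking-current range $[I_1, I_2]$ is identified by simulation sweep with
bisection refinement at the boundaries, mirroring how the underlying study
identifies it (no formal Hopf continuation).

## The scaled-conductance control

To separate "the currents changed" from "the membrane has memory", the
control model runs first-order dynamics with $g_{Na}, g_K, g_L$ rescaled so
that peak current magnitudes track those of a fractional run
(`scaled_first_order_patch()`, `scaled_first_order_cable()`).

An implementation finding worth recording: the *exact* joint match is
ill-posed.  Peak $|I_{Na}|$ and peak $|I_K|$ respond almost identically to
$g_{Na}$ and $g_K$ scaling (the log-sensitivity matrix measured around the
operating point has determinant $\approx 0.02$), so iterating the match below
a few percent drives the multipliers to extreme values (5-7x) at which the
cable becomes spontaneously active and the control is meaningless.  The patch
control therefore iterates with damping and stops when the residual stalls
(typically ~4%, flagged `converged = FALSE`); the cable control applies a
small number of damped ratio passes (default one), which yields exactly the
documented multiplier pattern — sodium up, potassium and leak down — and a
stable, physiological control cable.  One consequence: the control reproduces
the fractional model's spike-amplitude reduction only approximately (about
10-12% high at $\alpha = 0.6$, $I_{app} = 20$), while the qualitative
signature — the control *increases* spike frequency where the fractional
model decreases it — is robust.

## Networks

`generate_network()` draws each neuron's indegree from a Gaussian
($\mu = 25$, $\sigma = 2.5$, rounded, clipped to $[0, N]$), presynaptic
indices uniformly with replacement (self-loops allowed and counted), and
makes each synapse excitatory with probability 0.1.  Synapses are
instantaneous sigmoids $s(v_j) = 1/(1 + e^{-(v_j - V_{syn})/k_{syn}})$.
Activity is evoked by 40 µA/cm² for 50 ms in 13 randomly chosen neurons; the
summary includes the raster, the network-mean potential $\Lambda(t)$ (a
pseudo-EEG), 50-ms/10-ms sliding firing rates, pooled ISIs, the activity
duration (last spike time), a "sustained" flag (any spike in the final
50 ms), and the synaptic charges $Q_{synE}, Q_{synI}$ (trapezoidal integrals
of the network-averaged synaptic currents over the stimulus window).

**Synaptic constants are stand-ins.**  The reference values for the synapse
are not available, so the package documents its own: $V_{syn} = 20$ mV,
$k_{syn} = 2$ mV, $E_{syn,ex} = 70$ mV, $E_{syn,in} = -12$ mV (rest-relative)
and $g_{syn} = 0.15$ mS/cm².  A first-principles coincidence estimate (three
synchronously active excitatory inputs reaching the brief-pulse threshold)
suggests $g_{syn} \approx 0.025$, but at that strength — and indeed anywhere
below $\approx 0.15$ — the sparse excitatory connectivity (10% of synapses)
cannot regenerate activity, and *every* network falls silent at stimulus
offset regardless of order, which contradicts the defining first-order
baseline of the study (sustained activity at $\alpha = 1$).  $g_{syn}$ was
therefore fixed at the smallest round value restoring that baseline, chosen
from an $\alpha = 1$-only scan.  All network-level conclusions drawn with
these constants are trends across architectures (e.g. mean activity duration
lower at $\alpha = 0.4$ than at $\alpha = 1$ over 12 seeds), never calibrated
values.

## What the simulations do and do not show

The simulated conditions are idealized: deterministic channels, a single
neuron type, spatially uniform cables, random (not physiological)
connectivity, and stand-in synaptic constants.  Passing tests therefore
demonstrate that the numerics faithfully solve the stated fractional models
and that the documented qualitative phenomena (earlier spike peaks, reduced
amplitude, shrunken spiking range, faster propagation, earlier network
quiescence as $\alpha$ decreases) are genuine properties of those models —
not that any particular biological membrane has a particular $\alpha$.
Hour-scale memory effects are out of scope: the longest simulations here are
hundreds of milliseconds.

## Problem sizes used by the test suite and acceptance script

Chosen to characterize each result on a single CPU: patch runs of 100 ms at
$\Delta t = 10^{-3}$-$10^{-4}$ ms; cable runs of 12-25 ms on 21 nodes;
refractory bisections over four orders; spiking-range sweeps on an
8-µA/cm² grid with 0.5-µA/cm² boundary refinement for
$\alpha \in \{1, 0.8, 0.6\}$; network trends over 12 architectures of 50
neurons for 150-200 ms (compressed memory at $\alpha = 0.4$).  The
acceptance script (`scripts/acceptance.R`) recomputes the headline quantities
end to end in a few minutes.

## Known limitations

* Non-zero initial conditions for the fractional variable are not supported
  (the extra GL initialization term is deliberately out of scope); fractional
  variables must start at 0, i.e. states are measured relative to rest.
* The truncated-memory policy changes the model; use compressed when the
  full sum is too expensive.
* The Mittag-Leffler evaluator covers real arguments with
  $\beta \le \alpha + 1$ on the deep-negative axis — the parameter range the
  membrane theory uses — not the full complex plane.
* Adaptive stepping and predictor-corrector fractional solvers are not
  provided; the explicit GL scheme with per-order default steps is the single
  integration engine.
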