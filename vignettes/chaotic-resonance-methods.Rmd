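---
title: "Methods: hybrid-system analysis of chaotic resonance in the Izhikevich neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid-system analysis of chaotic resonance in the Izhikevich neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(izhcr)
```

## The model and why it is awkward

The Izhikevich neuron is a planar ODE with a state-dependent jump:

$$ v' = 0.04 v^2 + 5 v + 140 - u + I, \qquad u' = a(b v - u), $$

and, whenever the membrane potential reaches the firing threshold of 30 mV,
the reset $(v, u) \mapsto (c,\, u + d)$. Time is in ms, $v$ in mV, and the
remaining quantities in the model's own units. With
$(a, b, c, I) = (0.2, 2, -56, -99)$ and $d$ in the range $-17 \lesssim d
\lesssim -12$ the neuron fires chaotically; above $d \approx -11.8$ it
settles into periodic firing. The driven variant adds a weak sinusoid
$S(t) = A \sin(2 \pi f_0 t)$ to the voltage equation ($f_0$ in kHz, so
$f_0 = 0.1$ means a 10 ms period); `A = 0` reduces it exactly to the
autonomous model.

The jump is what makes the analysis interesting. A naive two-trajectory
Lyapunov estimate is corrupted every time the two copies reset at slightly
different times, and the uncorrected variational flow reports a positive
maximum exponent even on periodic orbits — the package reproduces that
artifact as a regression test (`use_saltation = FALSE`). The fix is the
*saltation matrix*: the first-order correction that carries a tangent
vector across a transversal event-plus-jump,

$$ S \;=\; D g + \frac{\big(f(x^+) - D g\, f(x^-)\big)\, n^{\top}}{n \cdot f(x^-)}, $$

which for this reset ($Dg = \mathrm{diag}\,[0, 1]$ extended with the $u$
row, $n = (1, 0)$) collapses to

$$ S_i = \begin{pmatrix} \dot v^+ / \dot v^- & 0 \\ (\dot u^+ - \dot u^-)/\dot v^- & 1 \end{pmatrix}. $$

`saltation_general()` implements the generic form (also used by the linear
calibration systems); `saltation_matrix()` the reset-specific one. Both
refuse tangential crossings ($|\dot v^-| < 10^{-12}$).

## Integration

Between events the system is integrated by `deSolve::lsodar` — the
root-finding variant of the Livermore multistep solver, which switches
automatically between Adams and backward-differentiation formulae — with
the right-hand side, the $2\times2$ variational system and the event
function compiled in C. Spike times come from the solver's own root
polishing. Defaults (`integrator_config()`): `rtol = 1e-10`,
`atol = 1e-12`, `hmax = 0.05` ms, event tolerance `1e-9` ms; chaotic
classifications in this model are known to be sensitive to sloppy event
handling, and at this system size tight tolerances cost little. Halving
the tolerances moves spike times of a 500 ms regular-spiking run by about
`1e-8` ms.

The variational system is integrated as a 6-dimensional augmented state
(2 state + 4 matrix entries) under the same tolerances, so the transition
matrix $\Phi$ inherits the trajectory's local error control. Each
inter-spike segment restarts $\Phi$ at the identity.

Defaults chosen where the problem leaves them open: initial condition
$(v_0, u_0) = (c,\, b c)$ at $t = 0$ (recorded in every run's metadata);
transient discard 3000 ms before any statistic is collected; the signal
phase uses absolute simulation time, so discarding a transient does not
reset the phase — cycle histograms fold by `t mod T0`, which presumes a
global clock.

## Lyapunov spectrum

`lyapunov_spectrum()` chains per-segment transition matrices with the
saltation matrices of the events between them, cuts the trajectory into
blocks of 20 spikes (or 1000 ms, whichever comes first, so non-firing
regimes still produce blocks), takes the eigenvalue moduli $l_j^k$ of each
block product, and reports

$$ \lambda_j = \frac{1}{T^N - T^0} \sum_{k} \log |l_j^k| $$

with natural logs (units 1/ms), branches paired by sorted modulus.
Eigenvalues per block — rather than a QR product across blocks — is the
procedure this analysis pipeline is defined around; the block products are
accumulated in a scaled representation (unit max-norm matrix plus a log
factor) so strongly expanding blocks cannot overflow. Two guards validate
it: linear hybrid systems with closed-form spectra (`make_linear_hybrid()`,
`make_sawtooth_hybrid()`; agreement within 2%), and the two-trajectory
divergence estimate `divergence_lyapunov()`, which is documented as
approximate near resets and is used only as a sign/magnitude cross-check.
A time cap that lands mid-segment simply ends the block there with the
partial segment's $\Phi$.

Regimes are labelled from $(\lambda_1, \lambda_2, CV)$ with
$\varepsilon_{chaos} = 10^{-3}$/ms and $\varepsilon_{CV} = 10^{-2}$
(`classify_regime()`): the source analysis says only "$\lambda_1 \approx
0$", so the numeric thresholds are ours.

## Poincaré section and the route to chaos

The section is the firing surface itself ($v = 30$), and the section
coordinate is the pre-reset $u_i$ at each upward crossing. Because any
trajectory leaves the surface instantly through the reset, the map
$\psi: u_i \mapsto u_{i+1}$ is evaluated by shooting from the post-reset
image $(c,\, u_0 + d)$ — the only self-consistent start for an arbitrary
$u_0$. `evaluate_psi()` co-propagates the variational system and chains
intermediate saltation matrices, so the derivative of the $l$-th iterate
comes from the same pass:

$$ \mu = \begin{pmatrix} 0 & 1 \end{pmatrix} P\, \Phi(t_l, t_0) \begin{pmatrix} 0 \\ 1 \end{pmatrix}, \qquad P = \begin{pmatrix} 0 & 0 \\ -\dot u / \dot v & 1 \end{pmatrix}, $$

with the flow in $P$ evaluated pre-reset at the terminal crossing. The
projection row divides by $\dot v$, the transversal component: a perturbed
trajectory crosses the surface at a slightly shifted time
$\delta t = -\delta v / \dot v$, displacing its section coordinate by
$-(\dot u/\dot v)\,\delta v$. (Printed forms of this projection sometimes
swap the two flow components; the finite-difference oracle
$\mu \approx (\psi^l(u^*+h) - \psi^l(u^*-h))/2h$, enforced at $10^{-3}$
relative in the tests, pins down the correct orientation.) Crossings with
$|\dot v|$ near zero raise an error rather than being regularized — they
do not occur on the attractors studied here.

Fixed points of $\psi^l$ are bracketed on a 400-point grid over the
admissible window (default $[-110, -75]$; the observed section ranges span
roughly $[-103, -80]$), polished with `uniroot`, and annotated with $\mu$.
Brackets that straddle a discontinuity of the map (the map has several
branches in the chaotic regime) are discarded by a residual check.
Sub-intervals where the map does not return within the time cap are
skipped — the map is undefined there.

`locate_tangent_bifurcation()` follows the stable fixed-point branch of
$\psi^2$ while bisecting on $d$: where the branch exists the sign of
$\mu - 1$ decides, and a $d$ where the continued root has vanished (the
stable/unstable pair has annihilated) counts as beyond the bifurcation, so
both the tangency and the pair-annihilation readings of the transition are
covered. On the canonical set the locator converges to
$d^* = -11.794 \pm 10^{-3}$, with $\mu \to 1$ from below along the branch;
$\lambda_1$ turns positive immediately below. Published descriptions of
this transition quote $d \approx -11.9$ at one-decimal precision; near the
onset the laminar episodes of the intermittent dynamics are extremely
long, so coarse bifurcation scans naturally read the transition slightly
low.

Intermittency is quantified on the section series:
`laminar_turbulent_stats()` labels index $i$ laminar when
$|u_{i+2} - u_i| < \delta$ (default $\delta = 0.5$ u-units, lag 2 to match
the $(u_i, u_{i+2})$ map on which the laminar channel lives) and reports
the laminar fraction and episode lengths. The fraction falls monotonically
from $d = -12$ (intermittent) to $d = -16$ (primarily turbulent).

## Signal-response metrics

The cycle histogram `cycle_histogram()` folds spike times into the phase
$\tilde t = ((t + T_0/2) \bmod T_0) - T_0/2 \in [-T_0/2, T_0/2)$ (so a
spike at $t = 6$ against $T_0 = 10$ sits at $\tilde t = -4$) and counts
them in 100 equal bins by default — 0.1 ms at $T_0 = 10$ ms, fine enough
to resolve the $|\tau| \approx 0.1$ ms delays seen at the edge of chaos.

`mutual_correlation()` computes, for each lag $\tau$ on a 0.05 ms grid
spanning one period, the Pearson correlation between the counts
$F(\tilde t)$ and the sinusoid evaluated *analytically* at the shifted bin
centers (no resampled signal, hence no second discretization error); bins
are weighted equally, ties in the maximum resolve to the smallest
$|\tau|$. `mutual_information()` discretizes the signal values at the bin
centers into $m_s = 20$ equal states over $[-A, A]$ and the counts into
$m_f = \min(20, \max F)$ equal states over $[0, \max F]$ — counts are
integers, so more states than the maximum count would be empty by
construction — and reports $MI = H(F) - H(F|S)$ in bits with occupancy
probabilities and the $0 \log 0 = 0$ convention. The signal-state
occupancy is *not* uniform (a sinusoid sampled uniformly in phase has an
arcsine amplitude density), which is why occupancies rather than assumed
weights are used.

### How long to simulate

The histogram is a counting measurement, so the observed correlation is
attenuated roughly like $C_{obs} \approx C_\infty / \sqrt{1 + \bar n_{noise}/\bar n_{sig}}$
with the per-bin Poisson-like fluctuation in the denominator. At the
canonical chaotic point ($d = -16$, $A = 0.3$) the measured maxima are
0.63 / 0.75 / 0.80 / 0.83 for 20 / 90 / 180 / 360 s of simulated time —
i.e. a few thousand signal periods are *not* enough for a stable maximum.
The package therefore uses 360 s (36 000 periods) for single-point
response quantities and 100–120 s per point inside sweeps, at which point
doubling the length moves the maximum correlation by under ~0.03. The
same effect biases the plug-in mutual information; the bias scales like
$(m_s - 1)(m_f - 1)/(2 N_{bins} \ln 2)$ in the number of *histogram bins*,
which is why the independence-baseline tests (uniform-phase Poisson
trains) are asserted under fine binning, where the closed-form nulls hold.

### What the synthetic generators do and do not emulate

`gen_locked_train()` (one spike per period at a set phase, wrapped-Gaussian
jitter) and `gen_uniform_train()` (homogeneous Poisson, uniform phase)
exist so every metric can be calibrated against closed forms: a jitter-free
locked train has $CV = 0$ and a single occupied bin; a narrow locked peak
at phase $\tilde t_0$ maximizes the correlation when the sinusoid's crest
aligns, at $\tau^* = T_0/4 - \tilde t_0$ (wrapped); Poisson trains give the
null correlation ($\mathrm{sd} \approx 1/\sqrt{N_{bins}}$) and the MI
bias floor. They are deliberately *not* neuron-like — no refractoriness,
no ISI correlations, no chaotic phase drift — so passing these
calibrations says the metrics are implemented correctly, not that the
neuron results generalize beyond the model. Seeds are mandatory arguments
and never touch the caller's RNG state. The linear hybrid systems play the
same role for the variational machinery: constant-matrix flows whose
transition matrices are matrix exponentials and whose spectra (with or
without contracting jumps) are known exactly.

## Sweeps and experiment drivers

`characterize_point()` is the per-point pipeline behind every sweep: one
variational pass for the spectrum (blocks as above), extended by a plain
fast simulation until the requested observation window is covered, then
ISI statistics, histogram, correlation and information, and a regime
label. Sweeps (`run_sweep()`) run in grid order, record per-point failures
in-row rather than aborting, can resume from their CSV output, and support
both cold starts (every point from $(c, bc)$; all headline numbers are
produced this way) and continuation (each point inherits the previous
final state, the conventional mode for bifurcation diagrams). The
pipeline contains no random number generator, so reruns are bit-identical.

`lambda_vs_response()` bins per-point $(\lambda_1, \max_\tau C)$ pairs by
$\lambda_1$ with a 0.001/ms window and averages within bins — the binned
curve is unimodal with its peak near $\lambda_1 \approx 0.04$/ms: weakly
chaotic orbits track the signal best, more strongly chaotic ones scramble
it, and periodic ones ignore it. `frequency_sweep()` exposes the resonance
in $f_0$ (peak near 0.103 kHz at $d = -12.19$, $A = 0.01$);
`locking_analysis()` maps the free-running / converging / locked zones of
the periodic regime (mean ISI 8.7 ms under weak drive, hard 1:1 locking at
10 ms under strong drive); `sensitivity_map()` scans $(d, A)$ and flags
the per-amplitude chaos threshold $d_{thr}$ and the "prompt" points
($\max_\tau C > 0.8$ and $|\tau| < 1.5$ ms).

Problem sizes used by the shipped acceptance script: 41-point $d$-sweep
(step 0.05) and 17-point $I$-sweep (step 0.5) with 80 blocks per point;
50-point response sweep at 120 s per point; three 360 s single-point
response runs; a 15-point frequency grid at 60 s per point.

## Numerical choices, degenerate inputs, limitations

* Spike events are *upward crossings* of $v = 30$ exactly (root of
  $v - 30$), not "$v > 30$ at a sample point"; a simulation ending mid-air
  at an event records the post-reset state as final.
* Zero spikes is a valid outcome everywhere (resting regime): spectra fall
  back to time-capped blocks, histograms are all-zero with $MI = 0$, and
  CV / mean ISI return `NA` with a warning (undefined, which is distinct
  from 0).
* Complex block eigenvalues use their moduli; branch pairing is by sorted
  modulus, which can momentarily swap branches at block boundaries — the
  sums are insensitive to this.
* The $\psi$ evaluation window is configurable; outside it, or when no
  return occurs within the time cap, the map is treated as undefined
  rather than extrapolated.
* Whether the signal term belongs in the flow values entering the
  saltation matrix is a genuine ambiguity for the driven system; the flow
  used is the full flow including $S(t)$ (the correction is exact for the
  system actually integrated), and at the amplitudes studied
  ($A \le 0.3$) the difference is far below the block-level noise.
* Limitations: exponents only for planar systems; no covariant Lyapunov
  vectors; period-doubling cascades are not tracked beyond detecting
  $\mu = -1$ crossings; no multi-neuron coupling.
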