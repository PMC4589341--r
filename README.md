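# izhcr — chaotic resonance in the Izhikevich neuron

`izhcr` is an R package for the dynamical analysis of the Izhikevich
spiking neuron, a hybrid system combining a smooth planar flow

```
v' = 0.04 v^2 + 5 v + 140 - u + I + A sin(2 pi f0 t)
u' = a (b v - u)
```

with a state-dependent reset: whenever the membrane potential `v` reaches
30 mV, `(v, u) -> (c, u + d)`. It is aimed at researchers studying
*chaotic resonance* — the amplification of a weak periodic signal by a
system's own chaotic fluctuations, with no added stochastic noise — and,
more generally, at anyone who needs correct stability analysis of reset
(hybrid) systems.

The reset breaks ordinary Lyapunov analysis: without a correction at the
jump, the variational flow reports a positive maximum exponent even on
periodic orbits. The package's core is the **saltation matrix**

```
S_i = [ vdot+/vdot-            0 ]
      [ (udot+ - udot-)/vdot-  1 ]
```

inserted into the chained transition matrices at every reset, giving the
spectrum `lambda_j = (1/(T^N - T^0)) sum_k log |l_j^k|` from per-block
eigenvalues (blocks of 20 spikes, 1000 ms cap). On top of that it provides:

* event-detecting stiff integration (`deSolve::lsodar`, compiled RHS) with
  co-propagated variational equations — `simulate_neuron()`,
* Poincaré analysis on the firing section `v = 30`: the return map
  `psi^l` by shooting, fixed points, the stability index
  `mu = d(psi^l)/du`, tangent-bifurcation localization, and
  laminar/turbulent intermittency statistics — `evaluate_psi()`,
  `find_fixed_points()`, `stability_mu()`, `locate_tangent_bifurcation()`,
  `laminar_turbulent_stats()`,
* weak-signal response metrics: the cycle histogram `F(t~)` of spike
  phases, the lagged mutual correlation `C(tau)` with its maximizer, and
  the mutual information `MI(F;S)` with the 20-state binning rule —
  `cycle_histogram()`, `mutual_correlation()`, `mutual_information()`,
* experiment drivers for parameter sweeps, the `lambda1`-vs-response
  curve, the frequency-resonance sweep, locking analysis and `(d, A)`
  sensitivity maps — `run_sweep()`, `lambda_vs_response()`,
  `frequency_sweep()`, `locking_analysis()`, `sensitivity_map()`,
* synthetic calibration inputs with closed-form properties: locked and
  Poisson spike trains, and linear hybrid systems whose transition
  matrices and Lyapunov spectra are known exactly —
  `gen_locked_train()`, `gen_uniform_train()`, `make_linear_hybrid()`,
  `make_sawtooth_hybrid()`.

Everything is deterministic: no random number generator enters the
dynamical pipeline (seeds appear only in the synthetic-train generators,
as mandatory arguments).

## Worked example

Characterize the canonical chaotic point (`a = 0.2, b = 2, c = -56,
I = -99, d = -16`) driven by a weak sinusoid:

```r
library(izhcr)
p  <- neuron_params(d = -16)              # canonical chaotic set
s  <- signal_params(A = 0.3, f0 = 0.1)    # 10 ms period
pt <- characterize_point(p, s, duration_ms = 60000, n_blocks = 100)
pt[, c("lambda1", "lambda2", "cv", "max_C", "tau_at_max", "MI", "regime")]
#>   lambda1 lambda2    cv max_C tau_at_max   MI  regime
#> 1  0.0922 0.00278 0.514 0.804         -3 1.68 chaotic
```

`lambda1 = 0.092/ms > 0` with `CV = 0.51` confirms chaotic, irregular
firing; yet the cycle histogram of spike phases tracks the weak input
closely (`max C = 0.80` at a 3 ms delay, `MI = 1.7` bits) — the chaotic
fluctuations are doing the work noise does in stochastic resonance. Note
the correlation keeps rising with observation time (counting noise in the
histogram attenuates it); 360 s runs give ~0.83. For contrast, the
periodic regime:

```r
lyapunov_spectrum(neuron_params(d = -10))
#> Lyapunov spectrum: lambda1 = -0.00001, lambda2 = -0.03164 [1/ms]  (200 blocks, 34702 ms)
```

`lambda1 ~ 0, lambda2 < 0`: a stable periodic orbit — which ignores the
same weak signal. The transition between the two regimes is a tangent
bifurcation of the second-iterate return map on the firing section;
`locate_tangent_bifurcation()` pins it at `d* = -11.794` (the stability
index `mu` of the tracked fixed point reaches 1 there).

Config-driven runs are available through `read_run_config()` /
`run_from_config()` (YAML in, CSV/JSON out, with a config echo and
manifest per run).

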