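---
title: "Rate dynamics of RS-LTS-FS cortical circuits with short-term plasticity"
author: "circuitrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate dynamics of RS-LTS-FS cortical circuits with short-term plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitrate)
```

## The model

`circuitrate` implements a firing-rate model of a neocortical microcircuit
with three neuronal populations: regular-spiking (RS) excitatory pyramidal
cells, low-threshold-spiking (LTS, somatostatin-positive) interneurons, and
fast-spiking (FS, parvalbumin-positive) interneurons. Each population is
described by an instantaneous rate

$$M_i = \beta_i\,[\,I_i + \textstyle\sum_j \pm\, g_{ij} s_{ij} - a_i - \theta_i\,]_+ ,$$

where $[\,\cdot\,]_+$ is the linear-threshold (rectification) function,
$\theta_i$ (nA) the firing threshold, $\beta_i$ (ms$^{-1}$nA$^{-1}$) the
steady-state gain, $I_i(t)$ the external (thalamic or neuromodulatory) drive
and $a_i$ an optional spike-frequency adaptation current. The sign of each
synaptic term is fixed by the presynaptic population: excitatory for RS,
inhibitory for LTS and FS.

Every synapse carries Tsodyks–Markram short-term plasticity with three state
variables — the open-channel fraction $s$, the available-resource fraction
$x$ (depression, recovery time $\tau_r$) and the running utilization $u$
(facilitation, recovery time $\tau_f$, baseline $U$):

$$\dot s = -s/\tau_s + u\,x\,M_{\text{pre}},\qquad
  \dot x = (1-x)/\tau_r - u\,x\,M_{\text{pre}},\qquad
  \dot u = (U-u)/\tau_f + U(1-u)\,M_{\text{pre}} .$$

Setting $\tau_r = 0$ pins $x \equiv 1$ and $\tau_f = 0$ pins $u \equiv U$;
these are exact algebraic pins, not small time constants, following the
convention that only the dominant plasticity process of each connection is
modelled. At a constant presynaptic rate $M$ the closed-form steady states
are $u^* = U(1+\tau_f M)/(1+U\tau_f M)$, $x^* = 1/(1+\tau_r u^* M)$ and
$s^* = \tau_s u^* x^* M$.

The reference circuit (`reference_circuit()`) wires the three populations
with eight synapses — there is no LTS-to-LTS chemical connection — using the
published parameter set: the RS-to-LTS synapse facilitates strongly
($\tau_f = 670$ ms, $U = 0.09$) while every other connection depresses.
Units are ms, nA and ms$^{-1}$ internally; rates are converted to Hz only at
reporting boundaries, because the gains are tabulated in
ms$^{-1}$nA$^{-1}$.

## Simulation

`simulate_circuit()` integrates the synaptic/adaptation state with the
classic fixed-step fourth-order Runge–Kutta scheme, default `dt = 0.02` ms,
recomputing the algebraic rates at every stage. Step-halving changes rate
samples by less than $10^{-8}$ ms$^{-1}$ on reference step responses, and the
integrator matches `deSolve::rk4` on an identical right-hand side to within
$10^{-12}$ (both checked in the test suite). The default initial state is a
long-rested network ($s=0$, $x=1$, $u=U$, $a=0$). Stimulus protocols are
constant, step, or periodic square waves; the square wave scales its
active-phase amplitude as $\langle I\rangle/\text{duty}$ so the mean drive is
fixed, mimicking absence-seizure-like thalamic input (default 3 Hz).

Spike-frequency adaptation uses the matched-gain construction: the
instantaneous gain is $\tilde\beta = \beta/(1-\beta\bar g_a)$ so that the
steady-state rate–current curve is identical with and without adaptation;
only the transient is stronger. The published adaptation-strength constants
could not be mapped unambiguously onto the three populations, so the
strengths are exposed as configuration (`gbar_a`) with neutral defaults; the
matched-gain identity holds for any choice, and the equivalence of the
steady-state curves is asserted in the tests to $10^{-9}$ ms$^{-1}$.

## Steady states, thresholds, stability

`solve_fixed_point()` enumerates rectification branches (candidate active
sets, at most $2^3$): within a branch the synaptic variables take their
closed forms, reducing the problem to root-finding on the active rates. A
candidate is accepted only if all assumed-active rates are positive and all
assumed-silent populations sit at or below threshold; exactness at the
branch boundaries is the reason for enumerating branches rather than
smoothing the rectifier, because the scientific quantities of interest
(recruitment thresholds) live exactly there. Scalar branches are solved by
sign-change bracketing on a graded rate grid (which also resolves the folds
of the recurrent-excitation branch); multi-population branches use damped
quasi-Newton iteration from several starting points. Stability comes from
the analytic Jacobian of the smooth vector field restricted to the fixed
point's branch; a point is stable when all eigenvalue real parts are below
$-10^{-9}$ ms$^{-1}$, and the analytic Jacobian is cross-checked against
numerical differentiation in the tests.

Closed-form results built on this machinery:

* `lts_threshold_input()` — the LTS recruitment threshold
  $I_{R,\mathrm{LTS,th}}$ solves $g_{LR}\, s^*_{LR}(M_R) + I_L = \theta_L$
  with $M_R = \beta_R (I_R - \theta_R)$; tonic LTS drive $I_L$ lowers it.
* `rs_gain_at_lts_threshold()` — the RS gain just above onset,
  $\beta_R / (1 + \beta_R g_{RL} U_{RL} \tau_{s,RL}\,\kappa)$ with $\kappa$
  the LTS recruitment slope; it scales as $1/g_{RL}$ for strong inhibition
  and is independent of $\tau_{r,RL}$.
* `fs_max_rate()` — the FS ceiling under strong RS drive, where the
  depressing RS-to-FS input saturates at $g_{FR}\tau_{s,FR}/\tau_{r,FR}$.
* `delay_time_closed_form()` — the LTS onset delay after a step, from the
  linear relaxation of $u_{LR}$ toward $u^*(M_R)$; it diverges
  logarithmically at threshold.

On the delay: the closed form treats $s_{LR}$ as instantaneously
equilibrated ($\tau_f \gg \tau_s$), so the simulated onset lags it by
roughly $\tau_{s,LR} \approx 2$ ms uniformly. Near threshold, where delays
are tens to hundreds of ms, the relative agreement is at the percent level;
far above threshold the delay itself shrinks to a few ms and the
quasi-steady-state approximation dominates the comparison. The tests assert
the $\tau_s$-scale absolute agreement rather than a uniform relative bound.

## Attractor metrics and regime mapping

`classify_attractor()` discards a transient (default 5 s, conservative
against the ~1 s convergence of the circuit's responses) and labels the
trajectory oscillatory when the RS peak-to-trough amplitude in the analysis
window exceeds $10^{-4}$ ms$^{-1}$; a population is active above
$10^{-5}$ ms$^{-1}$ (0.01 Hz). Both thresholds sit orders of magnitude below
modelled rates and above the integrator's noise floor. The RS "more-active
state" of a slow oscillation is marked by FS activity, with an RS-median
crossing marker as a cross-check; frequency comes from upward level
crossings and the duty cycle is the in-state fraction of whole cycles.
Oscillations below 15 Hz are tagged slow (the facilitation-driven rhythm,
~1–10 Hz), above it fast (the recurrent-excitation rhythm, ~20–60 Hz).

`phase_diagram()` classifies a grid of constant inputs $(I_R, I_F)$ from the
rested state. `method = "simulate"` integrates every point;
`method = "hybrid"` uses the fixed-point solver where a unique stable
equilibrium exists and simulates the rest, which is much faster and agrees
with full simulation off regime boundaries (asserted on probe grids).
`ray_sweep()`, `find_activation_threshold()` and
`find_oscillation_interval()` work along rays $I_F = r\, I_R$, mirroring the
coordinated variation of thalamic drive to RS and FS cells; bisection runs
to $10^{-4}$ nA and thresholds are reported at the two-decimal precision of
the published values.

## Fast–slow analysis of the slow oscillation

In the reduced circuit (`reduced_circuit()`: only L←R, R←L, F←R, L←F, no
depression) the facilitation $u_{LR}$ is the single slow variable. Freezing
it makes the fast subsystem algebraic, with two stable branches: an upper
branch (LTS silent, $M_R = \beta_R(I_R-\theta_R)$ independent of $u$) ending
at the LTS-onset knee $u^+$, and a lower branch (FS silent) beginning at the
FS-onset knee $u^-$. In the limit $\tau_f \to \infty$, $U \to 0$ with
$C = U\tau_f$ fixed, the slow flow is
$\tau_f\,\dot u = -u + C(1-u)M_R$ with nullcline $u = C M_R/(1+C M_R)$.
Slow relaxation oscillations require exactly three conditions
(`oscillation_conditions()`): bistability $u^+ > u^-$; the nullcline clears
the upper branch (its value at the upper rate exceeds $u^+$, so $u$ grows
there); and it clears the lower branch (it stays below $u^-$ at the FS-onset
rate — the lower branch's largest rate — so $u$ shrinks there). The
inequality orientations were frozen only after direct reduced-model
simulation over a 41×41 input grid agreed with the predictions at more than
95% of points, the disagreements confined to within one grid cell of the
band boundary — the residual of the finite-$\tau_f$ approximation
($U = 0.09$ is small but not zero).

`fast_slow_period()` integrates the exact facilitation kinetics along each
branch between the knees; at the published oscillatory operating point it
lands within ~12% of the simulated period (the $C$-limit form is reserved
for the phase diagram, where only sign information matters).
`oscillatory_band()` measures the $I_F$-width of the predicted oscillation
band; the band always lies below $\theta_F$ (FS need RS excitation to
participate) and its width stabilises, with linearly falling borders, above
a moderate $I_R$.

## A reproducibility caveat on the full-circuit oscillation

The faithful implementation of the published parameter tables reproduces the
interneuron recruitment thresholds, the regime layout of the steady-state
phase diagram, the closed-form asymptotics, the fast recurrent-excitation
oscillation and the entire reduced-circuit fast–slow story. It does not
reproduce the narrow slow-oscillation sliver of the *full* reference
circuit: simulations and linear stability agree that the rest state remains
(weakly) stable throughout the junction region where that sliver is
reported. A structural argument explains why: with the tabulated depressing
FS→LTS synapse the FS→LTS drive saturates at $g\,\tau_s/\tau_r = 0.05$ nA,
which cannot hold the LTS population silent up to the facilitation levels
the relaxation cycle requires; quadrupling that coupling opens the
oscillation window. We therefore treat the full-circuit slow-oscillation
coordinates as irreproducible from the printed parameter set, report what
the faithful model computes, and exercise the slow-oscillation science in
the reduced circuit, where it is fully quantitative. No parameter was
adjusted toward the published oscillation claims.

## Problem sizes and numerical choices

Defaults used throughout the package and its tests: integration step
0.02 ms; attractor analysis over a 5 s window after a 5 s transient;
bisection tolerances $10^{-4}$ nA on inputs; fixed-point residuals below
$10^{-10}$; phase diagrams on 81×81 grids over $[0, 0.6]$ nA (hybrid
classification), with the prediction–simulation concordance of the reduced
model evaluated on a 41×41 grid over $I_R \in [0.05, 0.6]$,
$I_F \in [0, 0.28]$ (the pane below the FS threshold, where the band lives).
Degenerate inputs are handled explicitly: populations or synapses absent
from a circuit simply drop out of the sums; thresholds report `Inf` when a
population can never be recruited; and the integrator aborts with the time
and variable index if activity diverges (possible with strong undepressed
recurrent excitation, whose loop gain exceeds one).

## Limitations

Rates are unbounded above (no firing-rate saturation), electrical coupling
between interneurons is not modelled, thalamocortical synapses carry no
plasticity, and the rate description itself assumes weak synchrony — sharply
transient responses are qualitative. The synthetic fixtures used by the test
suite (square-labelled traces, ±10% conductance perturbations) exercise the
estimators and the robustness of the regime layout; they do not emulate
biological variability beyond that.
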