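# circuitrate

Firing-rate models of a neocortical microcircuit of regular-spiking (RS)
pyramidal cells and two inhibitory interneuron classes — low-threshold-spiking
(LTS, somatostatin) and fast-spiking (FS, parvalbumin) — coupled by synapses
with Tsodyks–Markram short-term depression and facilitation. The package is
for computational neuroscientists studying how facilitating RS→LTS and
depressing LTS→RS / RS→FS synapses shape the circuit's response to thalamic
input: recruitment thresholds, response delays, regime (phase) diagrams, and a
facilitation-driven slow oscillation.

## The model

Each population has an instantaneous rectified-linear rate

    M_i = beta_i * [ I_i + sum_j (+/-) g_ij s_ij - a_i - theta_i ]_+

and every synapse carries the plasticity kinetics

    ds/dt = -s/tau_s + u x M_pre
    dx/dt = (1-x)/tau_r - u x M_pre        (x = 1 when tau_r = 0)
    du/dt = (U-u)/tau_f + U (1-u) M_pre    (u = U when tau_f = 0)

Provided on top of the fixed-step RK4 integrator (dt = 0.02 ms):
closed-form and numerical steady states with linear stability; LTS
recruitment thresholds and the logarithmically diverging LTS onset delay;
attractor classification with oscillation frequency/duty-cycle estimators;
two-parameter phase diagrams and fixed-ratio input sweeps; and a fast–slow
(relaxation-oscillation) analysis of the reduced circuit whose single slow
variable is the RS→LTS facilitation.

## Worked example

```r
library(circuitrate)

spec <- reference_circuit()          # published 3-population, 8-synapse set

## LTS recruitment threshold of the RS-LTS subcircuit (g_RR = 0, g_LR = 7.5)
sub <- circuit_spec(
  list(population("R", 0.1, 0.11), population("L", 0.05, 0.32)),
  list(synapse("L", "R", g = 35,  U = 0.3,  tau_s = 6.3, tau_r = 1250),
       synapse("R", "L", g = 7.5, U = 0.09, tau_s = 2,   tau_f = 670)))
lts_threshold_input(sub)$I_R
#> [1] 0.1764741

## delayed LTS onset after a step just above threshold
tr <- simulate_circuit(sub, protocol(R = stim_step(0.25)), t_end = 1500)
measure_lts_delay(tr)                     # ms
#> [1] 97.32807
delay_time_closed_form(sub, 0.25)         # facilitation-clock closed form
#> [1] 95.19783

## interneuron activation thresholds along the ray I_F = 1.4 I_R
find_activation_threshold(spec, "F", ratio = 1.4, bracket = c(0.05, 0.3))
#> [1] 0.1610535

## slow oscillation of the reduced circuit and its fast-slow account
rc <- reduced_circuit()
osc <- simulate_circuit(rc, protocol(R = stim_constant(0.29),
                                     F = stim_constant(0.232)), t_end = 10000)
classify_attractor(osc)
#> Attractor: oscillatory (slow, 1.06 Hz, duty 0.38)
#> Active populations: R, L, F
#> Mean rates (Hz): R = 12.491, L = 1.154, F = 8.293
oscillation_conditions(rc, 0.29, 0.232)
#> Fast-slow reduction (C = 60.3 ms)
#>   u+ = 0.5272, u- = 0.4284, upper-branch M_R = 0.0209 ms^-1
#>   bistable: TRUE, upper clear: TRUE, lower clear: TRUE -> oscillation
```

The threshold values match the published two-decimal figures (FS onset at
0.16 nA on the 1.4 ray); the closed-form delay tracks the simulated LTS
onset up to the ~2 ms quasi-steady-state lag of the synaptic open fraction;
and the three fast–slow conditions (fast-subsystem bistability plus
non-intersection of the slow nullcline with either branch) correctly predict
the reduced circuit's limit cycle. See `vignettes/circuit-dynamics.Rmd` for
the full account of the model, the numerical choices, and a reproducibility
caveat about the full-circuit slow-oscillation sliver.

A command-line driver for simulation, steady-state reports, sweeps and phase
diagrams is included at `inst/scripts/circuitrate-cli.R`.

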