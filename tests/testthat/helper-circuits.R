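# Shared fixture builders. All circuits are constructed in code; the RS-LTS
# and RS-FS subcircuits below use the conductance overrides of the published
# two-population analyses (g_LR = 7.5 for the RS-LTS pair).

rs_lts_circuit <- function(g_RL = 35, g_LR = 7.5, tau_r_RL = 1250,
                           g_RR = 0, adaptation = FALSE) {
  pops <- list(population("R", 0.1, 0.11,
                          tau_a = if (adaptation) 100 else NA,
                          gbar_a = if (adaptation) 2 else 0),
               population("L", 0.05, 0.32,
                          tau_a = if (adaptation) 100 else NA,
                          gbar_a = if (adaptation) 1 else 0))
  syns <- list(synapse("L", "R", g = g_RL, U = 0.3, tau_s = 6.3,
                       tau_r = tau_r_RL),
               synapse("R", "L", g = g_LR, U = 0.09, tau_s = 2,
                       tau_f = 670))
  if (g_RR > 0)
    syns <- c(syns, list(synapse("R", "R", g = g_RR, U = 0.21, tau_s = 2,
                                 tau_r = 463)))
  circuit_spec(pops, syns)
}

rs_fs_circuit <- function(g_RF = 50, g_RR = 20, g_FR = 25, g_FF = 5) {
  circuit_spec(
    list(population("R", 0.1, 0.11), population("F", 0.28, 0.35)),
    list(synapse("R", "R", g = g_RR, U = 0.21, tau_s = 2, tau_r = 463),
         synapse("F", "R", g = g_RF, U = 0.14, tau_s = 2, tau_r = 875),
         synapse("R", "F", g = g_FR, U = 0.30, tau_s = 2, tau_r = 227),
         synapse("F", "F", g = g_FF, U = 0.30, tau_s = 2, tau_r = 400)))
}

# relax the circuit under constant inputs and return the final rates
relaxed_rates <- function(spec, inputs, t_end = 8000) {
  waves <- lapply(inputs, stim_constant)
  tr <- simulate_circuit(spec, do.call(protocol, waves), t_end = t_end,
                         record_dt = 1)
  tr$rates[nrow(tr$rates), ]
}
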