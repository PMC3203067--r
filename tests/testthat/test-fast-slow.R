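test_that("the slow nullcline follows u = C M / (1 + C M)", {
  expect_equal(slow_nullcline(60.3, 0), 0)
  expect_equal(slow_nullcline(60.3, 1e9), 1, tolerance = 1e-6)
  expect_equal(slow_nullcline(60.3, 0.02), 0.5466909, tolerance = 1e-6)
  # consistency with the exact facilitation fixed point in the scaling limit:
  # tau_f -> Inf, U -> 0 with C = U tau_f held fixed
  M <- 0.013
  u_exact <- function(U, tau_f)
    synapse_steady_state(synapse("R", "L", 1, U, 2, tau_f = tau_f), M)$u
  expect_equal(u_exact(60.3 / 670000, 670000), slow_nullcline(60.3, M),
               tolerance = 1e-3)
})

test_that("fast-subsystem branches behave as the bifurcation diagram demands", {
  spec <- reduced_circuit()
  I_R <- 0.29; I_F <- 0.232
  sp <- saddle_points(spec, I_R, I_F)
  expect_true(sp$u_plus > 0 && sp$u_plus < 1)
  expect_true(sp$u_minus > 0 && sp$u_minus < sp$u_plus)

  # the upper-branch RS rate does not depend on u
  us <- seq(0.1, sp$u_plus - 1e-3, length.out = 5)
  MRs <- vapply(us, function(u) fast_branches(spec, I_R, I_F, u)$upper[["R"]],
                numeric(1))
  expect_equal(MRs, rep(0.11 * (I_R - 0.1), 5))
  # upper branch ends at u+, lower branch begins at u-
  expect_null(fast_branches(spec, I_R, I_F, sp$u_plus + 1e-4)$upper)
  expect_false(is.null(fast_branches(spec, I_R, I_F, sp$u_plus - 1e-4)$upper))
  expect_null(fast_branches(spec, I_R, I_F, sp$u_minus - 1e-4)$lower)
  expect_false(is.null(fast_branches(spec, I_R, I_F, sp$u_minus + 1e-4)$lower))

  # frozen-u branch rates agree with direct fixed points of the fast
  # subsystem (facilitation disabled at the frozen value)
  u0 <- 0.3
  frozen <- set_synapse(spec, "L<-R", tau_f = 0, U = u0)
  fp <- Filter(function(f) f$stable,
               solve_fixed_point(frozen, c(R = I_R, F = I_F)))
  br <- fast_branches(spec, I_R, I_F, u0)$upper
  expect_equal(fp[[1]]$rates[c("R", "L", "F")], br, tolerance = 1e-9)

  # without FS-to-LTS coupling the LTS onset involves only the direct drive
  nofs <- set_synapse(spec, "L<-F", g = 0)
  sp2 <- saddle_points(nofs, I_R, I_F)
  expect_equal(sp2$u_plus, 0.05 / (7.5 * 2 * 0.11 * (I_R - 0.1)))
})

test_that("saddle points move as the inputs and thresholds dictate", {
  spec <- reduced_circuit()
  s1 <- saddle_points(spec, 0.29, 0.232)
  s2 <- saddle_points(spec, 0.29, 0.242)
  expect_false(isTRUE(all.equal(s1$u_minus, s2$u_minus)))
  expect_gt(s2$u_minus, s1$u_minus)  # more FS drive -> FS onset at higher u
  # with the FS->LTS coupling removed, theta_L -> 0 drives the LTS-onset
  # knee toward u = 0 (the onset condition reduces to its direct drive term)
  sp_small <- set_synapse(circuit_spec(
    list(population("R", 0.1, 0.11), population("L", 1e-6, 0.32),
         population("F", 0.28, 0.35)),
    reduced_circuit()$synapses), "L<-F", g = 0)
  expect_lt(saddle_points(sp_small, 0.29, 0.232)$u_plus, 1e-4)
})

test_that("the three oscillation conditions hold at the published operating point", {
  spec <- reduced_circuit()
  oc <- oscillation_conditions(spec, 0.29, 0.232)
  expect_true(oc$bistable)
  expect_true(oc$upper_no_intersect)
  expect_true(oc$lower_no_intersect)
  expect_true(oc$oscillation)
  expect_equal(oc$C, 0.09 * 670)

  # losing bistability at large inputs leaves both interneuron types active
  expect_equal(oscillation_conditions(spec, 0.5, 0.26)$label, "ML>0,MF>0")
  # strong direct FS drive pins the system on the LTS-silent branch
  expect_equal(oscillation_conditions(spec, 0.6, 0.4)$label, "ML=0")
  # too little FS drive leaves a lower-branch rest state
  expect_equal(oscillation_conditions(spec, 0.29, 0.1)$label, "MF=0")
  # weak RS drive silences both interneuron populations
  expect_equal(oscillation_conditions(spec, 0.12, 0.05)$label, "ML=MF=0")
})

test_that("the limit cycle's facilitation excursion matches the saddle points", {
  spec <- reduced_circuit()
  sp <- saddle_points(spec, 0.29, 0.232)
  tr <- simulate_circuit(spec, protocol(R = stim_constant(0.29),
                                        F = stim_constant(0.232)),
                         t_end = 10000, record_dt = 0.5)
  w <- tr$time > 6000
  u_range <- range(tr$u[w, "L<-R"])
  expect_equal(u_range[1], sp$u_minus, tolerance = 0.05)
  expect_equal(u_range[2], sp$u_plus, tolerance = 0.05)
})

test_that("quasi-static sweeps of the frozen facilitation show hysteresis", {
  spec <- reduced_circuit()
  I_R <- 0.29; I_F <- 0.232
  sp <- saddle_points(spec, I_R, I_F)
  run_at <- function(u, init) {
    frozen <- set_synapse(spec, "L<-R", tau_f = 0, U = u)
    tr <- simulate_circuit(frozen, protocol(R = stim_constant(I_R),
                                            F = stim_constant(I_F)),
                           t_end = 1500, init = init, record_dt = 5)
    list(M = tr$rates[nrow(tr$rates), ], state = state_at(tr))
  }
  retune <- function(state, u) { state$u["L<-R"] <- u; state }
  # forward sweep: stay on the upper branch (LTS silent) until u+
  us <- seq(0.15, 0.65, by = 0.01)
  st <- NULL
  jump_down <- NA
  for (u in us) {
    r <- run_at(u, if (is.null(st)) NULL else retune(st, u))
    st <- r$state
    if (is.na(jump_down) && r$M[["L"]] > 1e-5) jump_down <- u
  }
  expect_equal(jump_down, sp$u_plus, tolerance = 0.03)
  # backward sweep: stay on the lower branch until u-
  st <- NULL
  jump_up <- NA
  for (u in rev(us)) {
    r <- run_at(u, if (is.null(st)) NULL else retune(st, u))
    st <- r$state
    if (is.na(jump_up) && r$M[["F"]] > 1e-5) jump_up <- u
  }
  expect_equal(jump_up, sp$u_minus, tolerance = 0.03)
  expect_gt(jump_down, jump_up)
})

test_that("the slow-dynamics period approximates the simulated period", {
  spec <- reduced_circuit()
  per_th <- fast_slow_period(spec, 0.29, 0.232)
  tr <- simulate_circuit(spec, protocol(R = stim_constant(0.29),
                                        F = stim_constant(0.232)),
                         t_end = 10000, record_dt = 0.5)
  fd <- oscillation_frequency_and_duty(tr, transient = 5000, window = 5000)
  expect_equal(per_th, fd$period, tolerance = 0.2)

  # doubling tau_f and halving U keeps C and roughly doubles the period
  slow2 <- set_synapse(spec, "L<-R", tau_f = 1340, U = 0.045)
  tr2 <- simulate_circuit(slow2, protocol(R = stim_constant(0.29),
                                          F = stim_constant(0.232)),
                          t_end = 16000, record_dt = 0.5)
  fd2 <- oscillation_frequency_and_duty(tr2, transient = 8000, window = 8000)
  expect_equal(fd2$period / fd$period, 2, tolerance = 0.2)
})

test_that("closed-form predictions agree with reduced-model simulation", {
  spec <- reduced_circuit()
  irs <- seq(0.2, 0.5, length.out = 11)
  ifs <- seq(0.16, 0.28, length.out = 11)
  agree <- 0
  for (IR in irs) for (IF_ in ifs) {
    pred <- oscillation_conditions(spec, IR, IF_)$oscillation
    tr <- simulate_circuit(spec, protocol(R = stim_constant(IR),
                                          F = stim_constant(IF_)),
                           t_end = 8000, record_dt = 2)
    w <- tr$rates[tr$time > 5000, "R"]
    sim <- (max(w) - min(w)) > 1e-4
    agree <- agree + (pred == sim)
  }
  expect_gt(agree / 121, 0.9)
})

test_that("the reduced phase diagram shows the published regime geometry", {
  spec <- reduced_circuit()
  pd <- reduced_phase_diagram(spec, seq(0.05, 0.6, by = 0.05),
                              seq(0, 0.28, by = 0.02))
  expect_setequal(setdiff(unique(pd$label), "MR=0"),
                  c("ML=MF=0", "MF=0", "ML=0", "ML>0,MF>0", "osc"))
  # the oscillatory band lies strictly below theta_F
  expect_true(all(pd$I_F[pd$label == "osc"] < 0.28))
  # borders of the band decrease with I_R
  b1 <- oscillatory_band(spec, 0.4)
  b2 <- oscillatory_band(spec, 0.5)
  expect_lt(b2$lower, b1$lower)
  expect_lt(b2$upper, b1$upper)
})
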