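test_that("fixed points satisfy the uncoupled and asymptotic closed forms", {
  # no LTS-to-RS feedback: exact rectified-linear curve
  free <- rs_lts_circuit(g_RL = 0)
  fp <- solve_fixed_point(free, c(R = 0.4))
  stable <- Filter(function(f) f$stable, fp)
  expect_length(stable, 1)
  expect_equal(stable[[1]]$rates[["R"]], 0.11 * 0.3, tolerance = 1e-10)

  # large input: constant reduction beta_R * g_RL * tau_s / tau_r
  spec <- rs_lts_circuit()
  fp2 <- solve_fixed_point(spec, c(R = 2))[[1]]
  reduction <- 0.11 * (2 - 0.1) - fp2$rates[["R"]]
  expect_equal(reduction, 0.11 * 35 * 6.3 / 1250, tolerance = 0.01)

  # relaxation-simulation oracle at the same input
  sim <- relaxed_rates(spec, list(R = 2))
  expect_equal(fp2$rates[["R"]], unname(sim["R"]), tolerance = 1e-6)
})

test_that("every returned fixed point has vanishing derivatives", {
  cases <- list(list(spec = rs_lts_circuit(), inputs = c(R = 0.4)),
                list(spec = reference_circuit(), inputs = c(R = 0.3, F = 0.25)),
                list(spec = reference_circuit(adaptation = TRUE),
                     inputs = c(R = 0.5, F = 0.4)),
                list(spec = rs_fs_circuit(), inputs = c(R = 0.29, F = 0.35)))
  for (cs in cases) {
    fps <- solve_fixed_point(cs$spec, cs$inputs)
    expect_gt(length(fps), 0)
    for (f in fps) expect_lt(f$residual, 1e-10)
  }
})

test_that("stable fixed points match the long-time limit of simulation", {
  # randomized circuits and inputs in the reference neighbourhood
  set.seed(7)
  n_ok <- 0
  for (i in 1:50) {
    spec <- fixture_random_circuit(seed = i)
    inputs <- c(R = runif(1, 0, 0.55), F = runif(1, 0, 0.55))
    tr <- simulate_circuit(spec, protocol(R = stim_constant(inputs[["R"]]),
                                          F = stim_constant(inputs[["F"]])),
                           t_end = 20000, record_dt = 5)
    sim <- tr$rates[nrow(tr$rates), ]
    mid <- tr$rates[which.min(abs(tr$time - 18000)), ]
    if (max(abs(sim - mid)) > 1e-7) next   # not converged to rest
    fps <- Filter(function(f) f$stable, solve_fixed_point(spec, inputs))
    if (!length(fps)) next
    dists <- vapply(fps, function(f) max(abs(f$rates - sim)), numeric(1))
    expect_lt(min(dists), 1e-6)
    n_ok <- n_ok + 1
  }
  expect_gt(n_ok, 40)
})

test_that("steady RS activity is monotone in the inhibitory couplings", {
  MR_of <- function(g_RL) {
    f <- Filter(function(f) f$stable,
                solve_fixed_point(rs_lts_circuit(g_RL = g_RL), c(R = 0.5)))
    f[[1]]$rates[["R"]]
  }
  curve <- vapply(c(0, 10, 20, 35, 50), MR_of, numeric(1))
  expect_true(all(diff(curve) <= 1e-12))

  MR_rf <- vapply(c(0, 25, 50), function(g) {
    f <- Filter(function(f) f$stable,
                solve_fixed_point(rs_fs_circuit(g_RF = g), c(R = 0.5, F = 0.35)))
    min(vapply(f, function(x) x$rates[["R"]], numeric(1)))
  }, numeric(1))
  expect_true(all(diff(MR_rf) <= 1e-12))
})

test_that("the high-rate gain approaches beta_R in every circuit", {
  for (spec in list(rs_lts_circuit(), reference_circuit())) {
    inputs <- function(IR) if (length(spec$populations) == 3)
      c(R = IR, F = 0.75 * IR) else c(R = IR)
    M <- function(IR) {
      f <- Filter(function(f) f$stable, solve_fixed_point(spec, inputs(IR)))
      f[[1]]$rates[["R"]]
    }
    gain <- (M(8.1) - M(8)) / 0.1
    expect_equal(gain, 0.11, tolerance = 0.02)
  }
})

test_that("LTS recruitment threshold matches theory and a sweep oracle", {
  spec <- rs_lts_circuit()
  th <- lts_threshold_input(spec)
  expect_equal(th$I_R, 0.1765, tolerance = 1e-3)

  # oracle: bisection on the steady-state LTS rate over I_R
  active <- function(IR) {
    f <- Filter(function(f) f$stable, solve_fixed_point(spec, c(R = IR)))
    f[[1]]$rates[["L"]] > 1e-9
  }
  lo <- 0.12; hi <- 0.3
  while (hi - lo > 1e-5) {
    mid <- (lo + hi) / 2
    if (active(mid)) hi <- mid else lo <- mid
  }
  expect_equal(th$I_R, (lo + hi) / 2, tolerance = 1e-4)

  # stronger RS-to-LTS coupling recruits LTS earlier; the limit is theta_R
  ths <- vapply(c(7.5, 15, 30, 1e6), function(g)
    lts_threshold_input(rs_lts_circuit(g_LR = g))$I_R, numeric(1))
  expect_true(all(diff(ths) < 0))
  expect_equal(ths[4], 0.1, tolerance = 1e-3)

  # tonic LTS input lowers the threshold
  expect_lt(lts_threshold_input(spec, I_L = 0.04)$I_R, th$I_R)
  # a barely-coupled circuit never recruits LTS
  expect_equal(lts_threshold_input(rs_lts_circuit(g_LR = 1e-9))$I_R, Inf)
})

test_that("RS gain just above LTS onset follows the closed form", {
  expect_equal(rs_gain_at_lts_threshold(rs_lts_circuit(g_RL = 0)), 0.11)
  g1 <- rs_gain_at_lts_threshold(rs_lts_circuit(g_RL = 17.5))
  g2 <- rs_gain_at_lts_threshold(rs_lts_circuit(g_RL = 35))
  expect_lt(g2, g1)
  expect_equal(g1 / g2, 2, tolerance = 0.2)  # ~1/g_RL scaling when large
  # the slope at onset does not depend on the depression recovery time
  expect_equal(rs_gain_at_lts_threshold(rs_lts_circuit(tau_r_RL = 150)),
               rs_gain_at_lts_threshold(rs_lts_circuit(tau_r_RL = 1250)))
  # oracle: finite difference of the steady-state curve just above onset
  spec <- rs_lts_circuit()
  th <- lts_threshold_input(spec)$I_R
  M <- function(IR) Filter(function(f) f$stable,
                           solve_fixed_point(spec, c(R = IR)))[[1]]$rates[["R"]]
  fd <- (M(th + 2e-3) - M(th + 1e-3)) / 1e-3
  expect_equal(rs_gain_at_lts_threshold(spec), fd, tolerance = 0.02)
})

test_that("the maximal FS rate solves the saturation balance", {
  spec0 <- rs_fs_circuit(g_FF = 0)
  expect_equal(fs_max_rate(spec0, 0.35),
               0.35 * (0.35 + 25 * 2 / 227 - 0.28))
  m1 <- fs_max_rate(rs_fs_circuit(g_FF = 5), 0.35)
  m2 <- fs_max_rate(rs_fs_circuit(g_FF = 15), 0.35)
  expect_lt(m2, m1)
  # regression value for the published RS-FS configuration, with the
  # simulated steady state at strong drive approaching it from below
  expect_equal(m1, 0.0935581, tolerance = 1e-6)
  sim <- relaxed_rates(rs_fs_circuit(g_FF = 5), list(R = 3, F = 0.35),
                       t_end = 10000)
  expect_lt(sim[["F"]], m1)
  expect_equal(sim[["F"]], m1, tolerance = 0.05)
})

test_that("LTS onset delay after a step follows the facilitation clock", {
  spec <- rs_lts_circuit()
  th <- lts_threshold_input(spec)$I_R
  expect_equal(delay_time_closed_form(spec, th * 0.99), Inf)
  # logarithmic divergence: equal multiplicative steps toward threshold add
  # roughly equal delay increments
  eps <- c(0.016, 0.008, 0.004, 0.002, 0.001)
  d <- vapply(eps, function(e) delay_time_closed_form(spec, th + e), numeric(1))
  incr <- diff(d)
  expect_true(all(incr > 0))
  expect_lt(sd(incr) / mean(incr), 0.25)
  # monotone decreasing in the input, small at strong drive
  grid <- vapply(seq(0.2, 0.42, by = 0.02), function(I)
    delay_time_closed_form(spec, I), numeric(1))
  expect_true(all(diff(grid) < 0))
  expect_lt(delay_time_closed_form(spec, 0.42), 5)

  # simulation comparison: the closed form neglects the tau_s-scale lag of
  # the open-channel variable, so agreement is to ~tau_s absolute
  for (I_R in c(0.25, 0.3, 0.35)) {
    tr <- simulate_circuit(spec, protocol(R = stim_step(I_R)), t_end = 1500)
    expect_equal(measure_lts_delay(tr), delay_time_closed_form(spec, I_R),
                 tolerance = 3.5 / delay_time_closed_form(spec, I_R))
  }
})

test_that("linear stability is computed from the branch-restricted Jacobian", {
  # all-silent state: eigenvalues are the negative reciprocal time constants
  spec <- rs_lts_circuit()
  fp <- solve_fixed_point(spec, c(R = 0.05))
  expect_length(fp, 1)
  expect_identical(fp[[1]]$active, character(0))
  ev <- sort(Re(fp[[1]]$eigenvalues))
  expect_equal(ev, sort(-1 / c(6.3, 2, 1250, 670)), tolerance = 1e-12)
  expect_true(fp[[1]]$stable)

  # analytic Jacobian agrees with numerical differentiation of the
  # branch-restricted vector field at an active fixed point
  spec3 <- reference_circuit(adaptation = TRUE)
  inputs <- c(R = 0.4, F = 0.35)
  f <- Filter(function(f) length(f$active) == 3,
              solve_fixed_point(spec3, inputs))[[1]]
  pack <- function(st) c(st$s, st$x[vapply(spec3$synapses, `[[`, 1, "tau_r") > 0],
                         st$u[vapply(spec3$synapses, `[[`, 1, "tau_f") > 0],
                         st$a)
  depr <- vapply(spec3$synapses, `[[`, 1, "tau_r") > 0
  facil <- vapply(spec3$synapses, `[[`, 1, "tau_f") > 0
  unpack <- function(y) {
    ns <- length(spec3$synapses)
    st <- default_state(spec3)
    st$s[] <- y[1:ns]
    st$x[depr] <- y[ns + seq_len(sum(depr))]
    st$u[facil] <- y[ns + sum(depr) + seq_len(sum(facil))]
    st$a[] <- y[(ns + sum(depr) + sum(facil) + 1):length(y)]
    st
  }
  branch_rhs <- function(y) {
    st <- unpack(y)
    M <- population_rates(spec3, st, inputs)
    d <- state_derivatives(spec3, st, M)
    pack(d)
  }
  y0 <- pack(structure(list(s = f$s, x = f$x, u = f$u, a = f$a),
                       class = "network_state"))
  Jnum <- pracma::jacobian(branch_rhs, y0)
  ev_num <- sort(Re(eigen(Jnum, only.values = TRUE)$values))
  ev_ana <- sort(Re(stability_eigenvalues(spec3, f)))
  expect_equal(ev_ana, ev_num, tolerance = 1e-6)
})

test_that("recurrent RS excitation creates a forbidden low-rate band", {
  # no recurrence: a single branch, continuous in the input
  r0 <- detect_rr_bistability(rs_lts_circuit(g_RR = 1e-9), I_R = 0.12)
  expect_false(r0$bistable)
  expect_true(is.na(r0$M_R_c))

  # without recurrence arbitrarily low stable rates exist just above onset
  spec0 <- rs_lts_circuit()
  low <- Filter(function(f) f$stable && f$rates[["R"]] > 0,
                solve_fixed_point(spec0, c(R = 0.105)))
  expect_lt(low[[1]]$rates[["R"]], 1e-3)

  # strong recurrence: no stable rest below a critical rate M_R,c -- the
  # forbidden band of low positive rates
  spec40 <- rs_lts_circuit(g_RR = 40)
  min_rates <- vapply(seq(0.10, 0.30, by = 0.02), function(IR) {
    st <- Filter(function(f) f$stable && f$rates[["R"]] > 0,
                 solve_fixed_point(spec40, c(R = IR), dense_starts = TRUE))
    min(vapply(st, function(f) f$rates[["R"]], numeric(1)))
  }, numeric(1))
  expect_gt(min(min_rates), 5e-3)
  r40 <- detect_rr_bistability(spec40, I_R = 0.2)
  expect_gt(r40$M_R_c, 5e-3)

  # faster recovery from depression boosts the recurrent drive
  MR_at <- function(tau_r) {
    spec <- circuit_spec(
      list(population("R", 0.1, 0.11), population("L", 0.05, 0.32)),
      list(synapse("L", "R", g = 35, U = 0.3, tau_s = 6.3, tau_r = 1250),
           synapse("R", "L", g = 7.5, U = 0.09, tau_s = 2, tau_f = 670),
           synapse("R", "R", g = 40, U = 0.21, tau_s = 2, tau_r = tau_r)))
    f <- Filter(function(f) f$stable && "R" %in% f$active,
                solve_fixed_point(spec, c(R = 0.3), dense_starts = TRUE))
    max(vapply(f, function(x) x$rates[["R"]], numeric(1)))
  }
  rates <- vapply(c(60, 463, 1000), MR_at, numeric(1))
  expect_true(all(diff(rates) < 0))
})
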