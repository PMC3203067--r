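# Regime (phase-diagram) mapping: grids over (I_R, I_F), fixed-ratio ray
# sweeps, and bisection for activation thresholds and oscillation intervals.

REGIME_LABELS <- c("MR=0", "ML=MF=0", "MF=0", "ML=0", "ML>0,MF>0", "osc")

#' Modify a synapse of an existing circuit
#'
#' Returns a copy of the circuit with selected parameters of one synapse
#' replaced (adding the synapse if absent).
#'
#' @param spec a [circuit_spec()].
#' @param name connection name, e.g. `"R<-R"` (post<-pre).
#' @param ... parameters to replace (`g`, `U`, `tau_s`, `tau_f`, `tau_r`).
#' @return The modified [circuit_spec()].
#' @export
set_synapse <- function(spec, name, ...) {
  repl <- list(...)
  parts <- strsplit(name, "<-", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("synapse name must look like 'post<-pre'")
  cur <- spec$synapses[[name]]
  args <- if (is.null(cur))
    list(pre = parts[2], post = parts[1], g = 0, U = 0.3, tau_s = 2)
  else cur[c("pre", "post", "g", "U", "tau_s", "tau_f", "tau_r")]
  args[names(repl)] <- repl
  spec$synapses[[name]] <- do.call(synapse, args)
  circuit_spec(spec$populations, spec$synapses)
}

regime_label <- function(report) {
  if (report$kind == "oscillatory") return("osc")
  act <- report$active
  if (!("R" %in% act)) return("MR=0")
  if (!("L" %in% act) && !("F" %in% act)) return("ML=MF=0")
  if (!("F" %in% act)) return("MF=0")
  if (!("L" %in% act)) return("ML=0")
  "ML>0,MF>0"
}

attractor_at <- function(spec, I_R, I_F, t_end = 10000, transient = 5000,
                         dt = 0.02, init = NULL) {
  waves <- list(R = stim_constant(I_R))
  if ("F" %in% pop_labels(spec) && I_F != 0) waves$F <- stim_constant(I_F)
  tr <- simulate_circuit(spec, do.call(protocol, waves),
                         t_end = t_end, dt = dt, init = init,
                         record_dt = 0.5)
  classify_attractor(tr, transient = transient, window = t_end - transient)
}

steady_label <- function(spec, I_R, I_F) {
  # fixed-point route: returns a rest label when a unique stable fixed point
  # exists, NA otherwise (caller falls back to simulation)
  fps <- solve_fixed_point(spec, c(R = I_R, F = I_F))
  stable <- Filter(function(f) f$stable, fps)
  if (length(stable) != 1) return(NA_character_)
  regime_label(list(kind = "rest",
                    active = stable[[1]]$active))
}

#' Two-parameter phase diagram of the steady-state behaviour
#'
#' Classifies the large-time attractor reached from the rested initial state
#' on a grid of constant inputs `(I_R, I_F)`. Labels: `"MR=0"` (RS
#' quiescent), `"ML=MF=0"`, `"MF=0"`, `"ML=0"`, `"ML>0,MF>0"` and `"osc"`.
#' `method = "simulate"` integrates every grid point (the dynamical ground
#' truth); `method = "hybrid"` uses the fixed-point solver for points with a
#' unique stable equilibrium and simulates only where equilibria are missing
#' or ambiguous, which is much faster on fine grids. When classification
#' near a boundary is ambiguous the simulation horizon is doubled once.
#'
#' @param spec a [circuit_spec()].
#' @param I_R_values,I_F_values grid values (nA).
#' @param method `"simulate"` or `"hybrid"`.
#' @param t_end,transient simulation horizon and discarded transient (ms).
#' @return A data.frame with columns `I_R`, `I_F`, `label`, `frequency`,
#'   `duty`.
#' @export
phase_diagram <- function(spec, I_R_values, I_F_values,
                          method = c("hybrid", "simulate"),
                          t_end = 10000, transient = 5000) {
  method <- match.arg(method)
  grid <- expand.grid(I_R = I_R_values, I_F = I_F_values,
                      KEEP.OUT.ATTRS = FALSE)
  lab <- character(nrow(grid))
  freq <- duty <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    IR <- grid$I_R[i]; IF_ <- grid$I_F[i]
    l <- if (method == "hybrid") steady_label(spec, IR, IF_) else NA_character_
    if (is.na(l)) {
      rep_ <- tryCatch(attractor_at(spec, IR, IF_, t_end, transient),
                       error = function(e) NULL)
      if (is.null(rep_))
        rep_ <- tryCatch(attractor_at(spec, IR, IF_, 2 * t_end, 2 * transient),
                         error = function(e) NULL)
      if (is.null(rep_)) {
        l <- "unclassified"
      } else {
        l <- regime_label(rep_)
        freq[i] <- rep_$frequency
        duty[i] <- rep_$duty
      }
    }
    lab[i] <- l
  }
  grid$label <- lab
  grid$frequency <- freq
  grid$duty <- duty
  grid
}

#' Sweep the inputs along a fixed-ratio ray
#'
#' Varies `I_R` with `I_F = ratio * I_R` and records, per point, the regime
#' label, the rest rates or limit-cycle extrema, and for oscillatory points
#' the frequency and more-active-state duty cycle.
#'
#' @param spec a [circuit_spec()].
#' @param ratio the fixed quotient `I_F / I_R`, nonnegative.
#' @param I_R_values sweep values (nA).
#' @param t_end,transient simulation horizon and discarded transient (ms).
#' @return A data.frame with `I_R`, `I_F`, `label`, per-population mean,
#'   min and max rates (ms^-1), `frequency` (Hz) and `duty`.
#' @export
ray_sweep <- function(spec, ratio, I_R_values, t_end = 10000,
                      transient = 5000) {
  stopifnot(ratio >= 0)
  getr <- function(v, lab) if (lab %in% names(v)) v[[lab]] else NA_real_
  rows <- lapply(I_R_values, function(IR) {
    rep_ <- attractor_at(spec, IR, ratio * IR, t_end, transient)
    data.frame(I_R = IR, I_F = ratio * IR, label = regime_label(rep_),
               M_R = getr(rep_$rates, "R"), M_L = getr(rep_$rates, "L"),
               M_F = getr(rep_$rates, "F"),
               M_R_min = rep_$min[["R"]], M_R_max = rep_$max[["R"]],
               frequency = rep_$frequency, duty = rep_$duty)
  })
  do.call(rbind, rows)
}

ray_steady_rate <- function(spec, population, IR, ratio,
                            method = c("steady", "simulate"),
                            t_end = 10000, transient = 5000) {
  method <- match.arg(method)
  if (method == "steady") {
    fps <- solve_fixed_point(spec, c(R = IR, F = ratio * IR))
    stable <- Filter(function(f) f$stable, fps)
    if (length(stable) == 1) return(stable[[1]]$rates[[population]])
  }
  rep_ <- attractor_at(spec, IR, ratio * IR, t_end, transient)
  rep_$rates[[population]]
}

#' Activation threshold of a population along a fixed-ratio ray
#'
#' Bisection on `I_R` (with `I_F = ratio * I_R`) for the onset of
#' steady-state activity of one population, judged by its attractor rate
#' exceeding 1e-5 ms^-1. The attractor is obtained from the fixed-point
#' solver, falling back to relaxation simulation when equilibria are
#' ambiguous.
#'
#' @param spec a [circuit_spec()].
#' @param population `"R"`, `"L"` or `"F"`.
#' @param ratio fixed `I_F / I_R`.
#' @param bracket length-2 `I_R` interval with the population silent at the
#'   low end and active at the high end.
#' @param tol bisection tolerance (nA).
#' @param method `"steady"` (fixed-point solves with simulation fallback) or
#'   `"simulate"`.
#' @return The threshold `I_R` (nA).
#' @export
find_activation_threshold <- function(spec, population, ratio, bracket,
                                      tol = 1e-4,
                                      method = c("steady", "simulate")) {
  method <- match.arg(method)
  act <- function(IR)
    ray_steady_rate(spec, population, IR, ratio, method) > EPS_M
  lo <- bracket[1]; hi <- bracket[2]
  if (act(lo)) stop("population already active at the lower bracket end")
  if (!act(hi)) stop("population still silent at the upper bracket end")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (act(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Slow-oscillation interval along a fixed-ratio ray
#'
#' Scans the bracket for oscillatory attractors (simulation from the rested
#' state, classification by RS-rate amplitude), then bisects the
#' oscillatory/rest boundary at both ends.
#'
#' @inheritParams find_activation_threshold
#' @param scan_step coarse scan step (nA) used to locate the interval.
#' @param t_end,transient simulation horizon and discarded transient (ms).
#' @return A list with `lower`, `upper` (nA) or `NULL` when no oscillatory
#'   point is found in the bracket.
#' @export
find_oscillation_interval <- function(spec, ratio, bracket, tol = 1e-4,
                                      scan_step = 0.005, t_end = 10000,
                                      transient = 5000) {
  osc <- function(IR)
    attractor_at(spec, IR, ratio * IR, t_end, transient)$kind == "oscillatory"
  xs <- seq(bracket[1], bracket[2], by = scan_step)
  flags <- vapply(xs, osc, TRUE)
  if (!any(flags)) return(NULL)
  i1 <- which(flags)[1]; i2 <- rev(which(flags))[1]
  bisect <- function(a, b, target_right) {
    # oscillatory on the side indicated by target_right
    while (b - a > tol) {
      mid <- (a + b) / 2
      if (osc(mid) == target_right) b <- mid else a <- mid
    }
    (a + b) / 2
  }
  lower <- if (i1 == 1) xs[1] else bisect(xs[i1 - 1], xs[i1], TRUE)
  upper <- if (i2 == length(xs)) xs[length(xs)]
           else bisect(xs[i2], xs[i2 + 1], FALSE)
  list(lower = lower, upper = upper)
}

high_activity_state <- function(spec, M_guess = 0.05) {
  # synaptic variables equilibrated to a common high rate; used as the second
  # initial condition when probing bistability
  st <- default_state(spec)
  for (k in seq_along(spec$synapses)) {
    ss <- synapse_steady_state(spec$synapses[[k]], M_guess)
    st$s[k] <- ss$s; st$x[k] <- ss$x; st$u[k] <- ss$u
  }
  st
}

#' Scan the recurrent RS-to-RS efficacy
#'
#' Brute-force scan over `g_RR`: for each value the circuit is simulated from
#' two initial conditions (long-rested, and synapses pre-equilibrated to a
#' high rate) to expose bistability between rest and fast-oscillation or
#' active states. Fast oscillations (tens of Hz) appear for large `g_RR`.
#'
#' @param spec a [circuit_spec()] containing an `R<-R` synapse slot.
#' @param I_R constant RS input (nA).
#' @param g_RR_values efficacies to scan.
#' @param I_F constant FS input (nA), default 0.
#' @param t_end,transient simulation horizon and discarded transient (ms).
#' @return A data.frame with `g_RR`, attractor kind from each initial
#'   condition, `bistable`, and oscillation `frequency` (Hz) where found.
#' @export
grr_scan <- function(spec, I_R, g_RR_values, I_F = 0, t_end = 6000,
                     transient = 3000) {
  rows <- lapply(g_RR_values, function(g) {
    sp <- if (is.null(spec$synapses[["R<-R"]]))
      set_synapse(spec, "R<-R", g = g, U = 0.21, tau_s = 2, tau_r = 463)
    else set_synapse(spec, "R<-R", g = g)
    r1 <- attractor_at(sp, I_R, I_F, t_end, transient)
    r2 <- attractor_at(sp, I_R, I_F, t_end, transient,
                       init = high_activity_state(sp))
    bist <- r1$kind != r2$kind ||
      max(abs(r1$rates - r2$rates)) > 10 * EPS_M
    f <- if (r1$kind == "oscillatory") r1$frequency
         else if (r2$kind == "oscillatory") r2$frequency else NA_real_
    data.frame(g_RR = g, kind_rested = r1$kind, kind_high = r2$kind,
               bistable = bist, frequency = f)
  })
  do.call(rbind, rows)
}
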