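# Fixed points, linear stability, thresholds and closed-form asymptotics.
#
# Fixed points are found by enumerating rectification branches (candidate
# active sets). Within a branch the synaptic variables take their closed-form
# steady states s* = tau_s u*(M) x*(M) M as functions of the presynaptic
# rate, so the problem reduces to root-finding on the active rates only.

STABILITY_TOL <- -1e-9

# Precompiled arithmetic for the steady-state balance. Adaptation cancels
# from the drive because a* = gbar_a M and the instantaneous gain is
# matched, so rates at steady state follow beta.
steady_env <- function(spec, inputs) {
  labels <- pop_labels(spec)
  I <- stats::setNames(rep(0, length(labels)), labels)
  I[names(inputs)] <- inputs
  post <- match(syn_char(spec, "post"), labels)
  incidence <- matrix(0, length(labels), length(post))
  for (k in seq_along(post)) incidence[post[k], k] <- 1
  list(labels = labels,
       npop = length(labels),
       base = unname(I - pop_field(spec, "theta")),
       beta = unname(pop_field(spec, "beta")),
       pre = match(syn_char(spec, "pre"), labels),
       post = post,
       incidence = incidence,
       gs = unname(syn_field(spec, "sign") * syn_field(spec, "g")),
       U = unname(syn_field(spec, "U")),
       tau_s = unname(syn_field(spec, "tau_s")),
       tau_f = unname(syn_field(spec, "tau_f")),
       tau_r = unname(syn_field(spec, "tau_r")))
}

# net drive (rectifier argument) per population at the closed-form synaptic
# steady state for the given full rate vector
env_drive <- function(e, rates) {
  # the closed forms degrade exactly to the pinned values at tau_f = 0
  # (u = U) and tau_r = 0 (x = 1), so no branching is needed
  M <- rates[e$pre]
  u <- e$U * (1 + e$tau_f * M) / (1 + e$U * e$tau_f * M)
  x <- 1 / (1 + e$tau_r * u * M)
  e$base + drop(e$incidence %*% (e$gs * e$tau_s * u * x * M))
}

# back-compatible named interface used by threshold/report code
steady_drive <- function(spec, rates, inputs) {
  e <- steady_env(spec, inputs)
  stats::setNames(env_drive(e, unname(rates[e$labels])), e$labels)
}

solve_active_branch <- function(e, active_idx, starts) {
  nact <- length(active_idx)

  resid <- function(Mact) {
    rates <- numeric(e$npop)
    rates[active_idx] <- Mact
    d <- env_drive(e, rates)
    Mact - e$beta[active_idx] * d[active_idx]
  }

  roots <- list()
  if (nact == 1) {
    # scalar branch: bracket every sign change on a graded grid (this also
    # resolves folds of the recurrent-excitation branch, which carry
    # multiple roots)
    xs <- c(seq(1e-8, 2e-3, length.out = 60),
            seq(2.5e-3, 0.1, length.out = 120),
            seq(0.11, 5, length.out = 80))
    fx <- vapply(xs, resid, numeric(1))
    flips <- which(fx[-1] * fx[-length(fx)] <= 0)
    for (i in flips) {
      M <- stats::uniroot(resid, c(xs[i], xs[i + 1]), tol = 1e-13)$root
      if (abs(resid(M)) > 1e-9 || M < 0) next
      dup <- any(vapply(roots, function(r) abs(r - M) < 1e-7, TRUE))
      if (!dup) roots[[length(roots) + 1]] <- M
    }
    return(roots)
  }
  # damped self-consistency iteration: converges near stable branches and
  # hands fsolve a start that polishes in a few steps
  it <- starts[[1]]
  for (j in 1:40) {
    rates <- numeric(e$npop)
    rates[active_idx] <- it
    it_new <- pmax(0.5 * it + 0.5 * e$beta[active_idx] *
                     env_drive(e, rates)[active_idx], 0)
    if (max(abs(it_new - it)) < 1e-14) { it <- it_new; break }
    it <- it_new
  }
  starts <- c(list(pmax(it, 1e-6)), starts)

  for (st in starts) {
    sol <- tryCatch(
      suppressWarnings(pracma::fsolve(resid, st, maxiter = 30, tol = 1e-13)),
      error = function(e) NULL)
    if (is.null(sol)) next
    M <- as.numeric(sol$x)
    if (any(!is.finite(M)) || max(abs(resid(M))) > 1e-9) next
    if (any(M < -1e-9)) next
    M <- pmax(M, 0)
    dup <- any(vapply(roots, function(r) max(abs(r - M)) < 1e-7, TRUE))
    if (!dup) roots[[length(roots) + 1]] <- M
  }
  roots
}

branch_starts <- function(e, active_idx, dense = FALSE) {
  base <- pmax(e$beta[active_idx] * e$base[active_idx], 1e-3)
  scales <- if (dense) c(0.05, 0.2, 0.5, 1, 2, 5, 20) else 1
  lapply(scales, function(sc) base * sc)
}

#' Solve for fixed points of the circuit under constant input
#'
#' Enumerates candidate active sets (rectification branches). Within a set
#' the synaptic variables take their closed-form steady states, reducing the
#' problem to root-finding on the active population rates; a candidate is
#' accepted only if all assumed-active rates are positive and every
#' assumed-silent population has net drive at or below threshold. Several
#' consistent fixed points may be returned (e.g. under recurrent-excitation
#' bistability).
#'
#' @param spec a [circuit_spec()].
#' @param inputs named constant external currents (nA).
#' @param active_set optional character vector restricting the search to one
#'   candidate active set.
#' @param dense_starts logical; use a denser grid of starting points (needed
#'   to expose folds of the recurrent-excitation branch).
#' @return A list of `fixed_point` objects, each with components `rates`,
#'   `s`, `x`, `u`, `a`, `active`, `eigenvalues`, `stable`, `residual`.
#'   Empty list if no consistent fixed point is found.
#' @export
solve_fixed_point <- function(spec, inputs = c(R = 0), active_set = NULL,
                              dense_starts = FALSE) {
  labels <- pop_labels(spec)
  e <- steady_env(spec, inputs)
  cand_sets <- if (!is.null(active_set)) list(match(active_set, labels)) else {
    sets <- list(integer(0))
    for (i in seq_along(labels))
      sets <- c(sets, lapply(sets, function(s) c(s, i)))
    sets
  }
  found <- list()
  for (active_idx in cand_sets) {
    if (!length(active_idx)) {
      d <- env_drive(e, numeric(e$npop))
      if (all(d <= 1e-12)) found <- c(found, list(make_fixed_point(
        spec, inputs, stats::setNames(numeric(e$npop), labels), character(0))))
      next
    }
    roots <- solve_active_branch(e, active_idx,
                                 branch_starts(e, active_idx, dense_starts))
    for (M in roots) {
      if (any(M <= 1e-12)) next                # not genuinely active
      rates <- numeric(e$npop)
      rates[active_idx] <- M
      d <- env_drive(e, rates)
      silent <- setdiff(seq_len(e$npop), active_idx)
      if (length(silent) && any(d[silent] > 1e-12)) next
      found <- c(found, list(make_fixed_point(spec, inputs,
                                              stats::setNames(rates, labels),
                                              labels[active_idx])))
    }
  }
  # deduplicate across candidate sets
  if (length(found) > 1) {
    keep <- rep(TRUE, length(found))
    for (i in seq_along(found)) for (j in seq_len(i - 1)) {
      if (keep[j] && max(abs(found[[i]]$rates - found[[j]]$rates)) < 1e-7)
        keep[i] <- FALSE
    }
    found <- found[keep]
  }
  found
}

make_fixed_point <- function(spec, inputs, rates, active) {
  sn <- names(spec$synapses)
  s <- x <- u <- stats::setNames(numeric(length(sn)), sn)
  for (k in seq_along(spec$synapses)) {
    syn <- spec$synapses[[k]]
    ss <- synapse_steady_state(syn, rates[[syn$pre]])
    s[k] <- ss$s; x[k] <- ss$x; u[k] <- ss$u
  }
  a <- vapply(spec$populations, function(p)
    if (p$adapt) p$gbar_a * rates[[p$label]] else 0, numeric(1))
  fp <- structure(list(rates = rates, s = s, x = x, u = u,
                       a = stats::setNames(a, pop_labels(spec)),
                       active = active, inputs = inputs),
                  class = "fixed_point")
  ev <- stability_eigenvalues(spec, fp)
  fp$eigenvalues <- ev
  fp$stable <- if (length(ev)) max(Re(ev)) < STABILITY_TOL else TRUE
  st <- structure(list(s = s, x = x, u = u, a = fp$a), class = "network_state")
  dv <- state_derivatives(spec, st, rates)
  fp$residual <- max(abs(unlist(dv)))
  fp
}

#' @export
print.fixed_point <- function(x, ...) {
  cat("Fixed point; active set {", paste(x$active, collapse = ", "), "};",
      if (x$stable) "stable" else "unstable", "\n")
  cat("Rates (Hz):",
      paste(sprintf("%s = %.3f", names(x$rates), 1000 * x$rates),
            collapse = ", "), "\n")
  invisible(x)
}

#' Linear stability of a fixed point
#'
#' Assembles the Jacobian of the smooth vector field restricted to the fixed
#' point's rectification branch (active populations keep their instantaneous
#' gain, silent populations contribute zero gain) by analytic differentiation
#' of the synaptic and adaptation kinetics, chained through the algebraic
#' rate equations. Coordinates pinned by `tau_r = 0` / `tau_f = 0` are not
#' dynamical and are excluded. The point is stable when every eigenvalue has
#' real part below `-1e-9` ms^-1.
#'
#' @param spec a [circuit_spec()].
#' @param fp a `fixed_point` (or a list with `rates`, `s`, `x`, `u`, `a`,
#'   `active`).
#' @return Complex eigenvalue vector (ms^-1).
#' @export
stability_eigenvalues <- function(spec, fp) {
  labels <- pop_labels(spec)
  nsyn <- length(spec$synapses)
  tau_s <- syn_field(spec, "tau_s"); tau_f <- syn_field(spec, "tau_f")
  tau_r <- syn_field(spec, "tau_r"); U <- syn_field(spec, "U")
  gg <- syn_field(spec, "g"); sg <- syn_field(spec, "sign")
  pre <- syn_char(spec, "pre"); post <- syn_char(spec, "post")
  adapt <- vapply(spec$populations, `[[`, TRUE, "adapt")

  # branch gains
  b <- ifelse(labels %in% fp$active, pop_field(spec, "beta_tilde"), 0)
  names(b) <- labels

  # coordinates: s_k (all), x_k (tau_r>0), u_k (tau_f>0), a_i (adapt)
  coords <- c(sprintf("s%d", seq_len(nsyn)),
              sprintf("x%d", which(tau_r > 0)),
              sprintf("u%d", which(tau_f > 0)),
              sprintf("a%d", which(adapt)))
  n <- length(coords)
  if (n == 0) return(complex(0))
  idx <- stats::setNames(seq_len(n), coords)
  J <- matrix(0, n, n, dimnames = list(coords, coords))

  # dM_i/d(coord): rates depend on s (incoming synapses) and a_i
  dM <- matrix(0, length(labels), n, dimnames = list(labels, coords))
  for (k in seq_len(nsyn))
    dM[post[k], idx[[paste0("s", k)]]] <- b[post[k]] * sg[k] * gg[k]
  for (i in which(adapt))
    dM[labels[i], idx[[paste0("a", i)]]] <- -b[labels[i]]

  M <- fp$rates
  for (k in seq_len(nsyn)) {
    Mj <- M[[pre[k]]]
    uk <- fp$u[[k]]; xk <- fp$x[[k]]
    dMj <- dM[pre[k], ]
    # ds_k/dt = -s/tau_s + u x M_j
    row <- uk * xk * dMj
    row[idx[[paste0("s", k)]]] <- row[idx[[paste0("s", k)]]] - 1 / tau_s[k]
    if (tau_r[k] > 0) row[idx[[paste0("x", k)]]] <-
        row[idx[[paste0("x", k)]]] + uk * Mj
    if (tau_f[k] > 0) row[idx[[paste0("u", k)]]] <-
        row[idx[[paste0("u", k)]]] + xk * Mj
    J[idx[[paste0("s", k)]], ] <- row
    # dx_k/dt = (1-x)/tau_r - u x M_j
    if (tau_r[k] > 0) {
      row <- -uk * xk * dMj
      row[idx[[paste0("x", k)]]] <- row[idx[[paste0("x", k)]]] -
        1 / tau_r[k] - uk * Mj
      if (tau_f[k] > 0) row[idx[[paste0("u", k)]]] <-
          row[idx[[paste0("u", k)]]] - xk * Mj
      J[idx[[paste0("x", k)]], ] <- row
    }
    # du_k/dt = (U-u)/tau_f + U (1-u) M_j
    if (tau_f[k] > 0) {
      row <- U[k] * (1 - uk) * dMj
      row[idx[[paste0("u", k)]]] <- row[idx[[paste0("u", k)]]] -
        1 / tau_f[k] - U[k] * Mj
      J[idx[[paste0("u", k)]], ] <- row
    }
  }
  for (i in which(adapt)) {
    p <- spec$populations[[i]]
    row <- p$gbar_a * dM[labels[i], ] / p$tau_a
    row[idx[[paste0("a", i)]]] <- row[idx[[paste0("a", i)]]] - 1 / p$tau_a
    J[idx[[paste0("a", i)]], ] <- row
  }
  eigen(J, only.values = TRUE)$values
}

#' LTS recruitment threshold in the RS-LTS subcircuit
#'
#' With no recurrent RS excitation the RS rate below LTS onset is simply
#' `M_R = beta_R (I_R - theta_R)`, and LTS neurons turn on when the
#' facilitating RS-to-LTS drive crosses their threshold:
#' `g_LR s*_LR(M_R) + I_L = theta_L`. The boundary rate `M_R,th` solves this
#' scalar condition, and the threshold input is
#' `I_R,th = theta_R + M_R,th / beta_R`. Tonic LTS input `I_L` lowers the
#' threshold.
#'
#' @param spec an RS-LTS(-FS) circuit with no recurrent RS-to-RS efficacy.
#' @param I_L tonic external input to the LTS population (nA).
#' @return A list of class `threshold_result` with `I_R` (nA; `Inf` if LTS
#'   are never recruited), `M_R_th` (ms^-1) and `population = "L"`.
#' @export
lts_threshold_input <- function(spec, I_L = 0) {
  if (!is.null(spec$synapses[["R<-R"]]) && spec$synapses[["R<-R"]]$g > 0)
    stop("closed-form LTS threshold requires zero RS-to-RS efficacy")
  lr <- spec$synapses[["L<-R"]]
  if (is.null(lr)) stop("circuit has no RS-to-LTS synapse")
  thL <- spec$populations[["L"]]$theta
  cond <- function(M) lr$g * synapse_steady_state(lr, M)$s + I_L - thL
  thR <- spec$populations[["R"]]$theta
  bR <- spec$populations[["R"]]$beta
  if (cond(0) >= 0) {
    M_th <- 0
  } else {
    hi <- 1
    while (cond(hi) < 0 && hi < 1e6) hi <- hi * 10
    if (cond(hi) < 0)
      return(structure(list(I_R = Inf, M_R_th = Inf, population = "L"),
                       class = "threshold_result"))
    M_th <- stats::uniroot(cond, c(0, hi), tol = 1e-12)$root
  }
  structure(list(I_R = thR + M_th / bR, M_R_th = M_th, population = "L"),
            class = "threshold_result")
}

# d/dM of u*(M) * M for a facilitating, non-depressing synapse
facil_drive_slope <- function(syn, M) {
  U <- syn$U; f <- syn$tau_f
  D <- 1 + U * f * M
  (U * (1 + 2 * f * M) * D - U * M * (1 + f * M) * U * f) / D^2
}

#' RS gain just above the LTS recruitment threshold
#'
#' Slope `dM_R/dI_R` of the steady-state RS rate-current curve immediately
#' above LTS onset, where the LTS-to-RS synapse has not yet depressed
#' (`s_RL ~ U_RL tau_s_RL M_L`). The slope follows from implicit
#' differentiation of the two-population balance:
#' `gain = beta_R / (1 + beta_R g_RL U_RL tau_s_RL kappa)` with
#' `kappa = beta_L g_LR tau_s_LR d(u* M)/dM` at the boundary rate. For large
#' `g_RL` the gain scales like `1/g_RL`; it does not depend on the LTS-to-RS
#' depression time constant.
#'
#' @inheritParams lts_threshold_input
#' @return The gain (ms^-1 nA^-1).
#' @export
rs_gain_at_lts_threshold <- function(spec, I_L = 0) {
  th <- lts_threshold_input(spec, I_L)
  bR <- spec$populations[["R"]]$beta
  rl <- spec$synapses[["R<-L"]]
  if (is.null(rl) || rl$g == 0) return(bR)
  lr <- spec$synapses[["L<-R"]]
  bL <- spec$populations[["L"]]$beta
  kappa <- bL * lr$g * lr$tau_s * facil_drive_slope(lr, th$M_R_th)
  bR / (1 + bR * rl$g * rl$U * rl$tau_s * kappa)
}

#' Maximal FS rate under strong RS drive
#'
#' In the RS-FS circuit the depressing RS-to-FS synapse saturates for large
#' RS rates: its open fraction tends to `tau_s_FR / tau_r_FR`, so the FS rate
#' approaches a constant `M_F,max` solving the scalar implicit balance
#' `M = beta_F (I_F + g_FR tau_s_FR / tau_r_FR - g_FF s*_FF(M) - theta_F)`.
#' With no FS-to-FS coupling the equation is explicit. Increasing `g_FF`
#' lowers `M_F,max`.
#'
#' @param spec a circuit containing an F<-R depressing synapse.
#' @param I_F constant external input to the FS population (nA).
#' @return `M_F,max` (ms^-1).
#' @export
fs_max_rate <- function(spec, I_F) {
  fr <- spec$synapses[["F<-R"]]
  if (is.null(fr)) stop("circuit has no RS-to-FS synapse")
  if (fr$tau_r <= 0)
    stop("RS-to-FS input does not saturate without depression (tau_r = 0)")
  sat <- fr$g * fr$tau_s / fr$tau_r
  pF <- spec$populations[["F"]]
  ff <- spec$synapses[["F<-F"]]
  drive0 <- I_F + sat - pF$theta
  if (is.null(ff) || ff$g == 0) return(pF$beta * rectify(drive0))
  h <- function(M) M - pF$beta *
    rectify(drive0 - ff$g * synapse_steady_state(ff, M)$s)
  hi <- pF$beta * rectify(drive0) + 1
  if (h(0) >= 0) return(0)
  stats::uniroot(h, c(0, hi), tol = 1e-12)$root
}

#' Closed-form delay of LTS recruitment after a step input
#'
#' For a step `I_R` above the LTS threshold (RS-LTS subcircuit, no recurrent
#' RS excitation) the RS rate is constant, `M_R = beta_R (I_R - theta_R)`,
#' during the delay, and the facilitation variable follows a linear relaxation
#' from `U` toward `u*(M_R)` with effective time constant
#' `1 / (1/tau_f + U M_R)`. LTS neurons turn on when `u` reaches
#' `u_th = theta_L / (g_LR tau_s_LR M_R)`; the delay is the log-time of that
#' crossing and diverges logarithmically as `I_R` approaches the threshold
#' from above.
#'
#' @inheritParams lts_threshold_input
#' @param I_R step amplitude (nA).
#' @return Delay (ms); `Inf` when `u*(M_R) <= u_th` (input at or below the
#'   recruitment threshold).
#' @export
delay_time_closed_form <- function(spec, I_R, I_L = 0) {
  lr <- spec$synapses[["L<-R"]]
  pR <- spec$populations[["R"]]
  thL <- spec$populations[["L"]]$theta
  M_R <- pR$beta * rectify(I_R - pR$theta)
  if (M_R <= 0) return(Inf)
  u_th <- (thL - I_L) / (lr$g * lr$tau_s * M_R)
  u_star <- synapse_steady_state(lr, M_R)$u
  if (u_th <= lr$U) return(0)
  if (u_star <= u_th) return(Inf)
  tau_eff <- 1 / (1 / lr$tau_f + lr$U * M_R)
  tau_eff * log((u_star - lr$U) / (u_star - u_th))
}

#' Bistability from recurrent RS excitation
#'
#' With a strong depressing RS-to-RS synapse the active-RS branch of fixed
#' points can fold: a stable active state exists only above a critical rate
#' `M_R,c`, producing a forbidden band of low positive rates and bistability
#' with the silent state. This routine enumerates the fixed points at the
#' given input and, when the active branch folds, traces it downward in
#' `I_R` to report the branch-end rate as `M_R,c`.
#'
#' @param spec a circuit with an R<-R synapse.
#' @param I_R external RS input (nA).
#' @param trace_step step (nA) used when tracing the branch downward.
#' @return A list with `fixed_points`, logical `bistable`, and `M_R_c`
#'   (ms^-1; `NA` when the branch extends continuously to zero rate).
#' @export
detect_rr_bistability <- function(spec, I_R, trace_step = 0.002) {
  fps <- solve_fixed_point(spec, c(R = I_R), dense_starts = TRUE)
  stable <- Filter(function(f) f$stable, fps)
  bistable <- length(stable) > 1
  M_R_c <- NA_real_
  seen_bistable <- bistable
  act <- Filter(function(f) "R" %in% f$active && f$stable, fps)
  if (length(act)) {
    # follow the stable active branch downward until it disappears; the
    # branch-end rate is the critical rate only when the silent state
    # coexists somewhere along the way (forbidden low-rate band)
    cur <- I_R
    last_rate <- act[[1]]$rates[["R"]]
    repeat {
      cur <- cur - trace_step
      if (cur < 0) { last_rate <- 0; break }
      fps2 <- solve_fixed_point(spec, c(R = cur), dense_starts = TRUE)
      if (length(Filter(function(f) f$stable, fps2)) > 1) seen_bistable <- TRUE
      act2 <- Filter(function(f) "R" %in% f$active && f$stable, fps2)
      if (!length(act2)) break
      last_rate <- min(vapply(act2, function(f) f$rates[["R"]], numeric(1)))
      if (last_rate < 1e-9) { last_rate <- 0; break }
    }
    if (seen_bistable && last_rate > 1e-6) M_R_c <- last_rate
  }
  list(fixed_points = fps, bistable = bistable, M_R_c = M_R_c)
}
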