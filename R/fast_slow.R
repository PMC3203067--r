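# Fast-slow (relaxation-oscillation) analysis of the reduced RS-LTS-FS
# circuit. With tau_r = 0 everywhere the only slow variable is the
# facilitation u of the RS-to-LTS synapse; every other synaptic variable
# relaxes on the tau_s scale. Freezing u turns the fast subsystem into an
# algebraic problem whose stable equilibria form two branches:
#
#   upper: M_L = 0, M_F >= 0, M_R = beta_R (I_R - theta_R)  (u-independent)
#   lower: M_F = 0, M_L > 0, (M_R, M_L) solve a linear 2x2 system in which
#          the RS->LTS coupling is g_LR tau_s_LR u M_R.
#
# The branches end at saddle-node values u+ (LTS onset on the upper branch)
# and u- (FS onset on the lower branch). In the limit tau_f -> Inf, U -> 0
# with C = U tau_f fixed, du/dt = (1/tau_f) (-u + C (1 - u) M_R) and the
# slow nullcline is u = C M_R / (1 + C M_R). Slow oscillations require
# bistability (u+ > u-) plus non-intersection of the nullcline with either
# branch over its existence range, so that u grows along the upper branch
# and shrinks along the lower one.

reduced_params <- function(spec) {
  need <- c("L<-R", "R<-L", "F<-R", "L<-F")
  for (nm in need)
    if (is.null(spec$synapses[[nm]]))
      stop("reduced circuit must contain the ", nm, " synapse")
  extra <- setdiff(names(spec$synapses)[syn_field(spec, "g") > 0], need)
  if (length(extra))
    stop("reduced analysis does not admit extra connections: ",
         paste(extra, collapse = ", "))
  if (any(syn_field(spec, "tau_r") > 0))
    stop("reduced circuit must have tau_r = 0 for all synapses")
  lr <- spec$synapses[["L<-R"]]
  if (lr$tau_f <= 0) stop("the L<-R synapse must facilitate")
  ps <- spec$populations
  list(
    beta = vapply(ps, `[[`, numeric(1), "beta"),
    theta = vapply(ps, `[[`, numeric(1), "theta"),
    # static effective couplings g * tau_s * U (u pinned at U)
    gam_RL = with(spec$synapses[["R<-L"]], g * tau_s * U),
    gam_FR = with(spec$synapses[["F<-R"]], g * tau_s * U),
    gam_LF = with(spec$synapses[["L<-F"]], g * tau_s * U),
    # the frozen-u coupling of the facilitating synapse is g * tau_s * u
    k_LR = lr$g * lr$tau_s,
    C = lr$U * lr$tau_f,
    U_LR = lr$U, tau_f_LR = lr$tau_f)
}

#' Slow nullcline of the facilitation variable
#'
#' In the limit of slow, weak facilitation (`tau_f -> Inf`, `U -> 0`,
#' `C = U tau_f` fixed) the facilitation variable of the RS-to-LTS synapse
#' obeys `tau_f du/dt = -u + C (1 - u) M_R`; its nullcline is
#' `u = C M_R / (1 + C M_R)`.
#'
#' @param C lumped slow constant `U_LR * tau_f_LR` (ms).
#' @param M_R RS rate (ms^-1), vectorised.
#' @return Nullcline value of `u`, in `[0, 1)`.
#' @export
slow_nullcline <- function(C, M_R) {
  stopifnot(all(M_R >= 0))
  C * M_R / (1 + C * M_R)
}

#' Equilibrium branches of the fast subsystem at frozen facilitation
#'
#' Equilibrates the fast synaptic variables at a fixed value `u` of the
#' RS-to-LTS facilitation and returns the rates on the two stable branches
#' where each exists: the upper branch (LTS silent) and the lower branch
#' (FS silent). Existence is checked by the sign of the silent population's
#' net drive (and positivity of the active rates).
#'
#' @param spec a reduced circuit (see [reduced_circuit()]).
#' @param I_R,I_F constant inputs (nA).
#' @param u frozen facilitation value in `[0, 1]`.
#' @return A list with components `upper` and `lower`, each either `NULL`
#'   (branch absent at this `u`) or a named rate vector `c(R =, L =, F =)`.
#' @export
fast_branches <- function(spec, I_R, I_F, u) {
  p <- reduced_params(spec)
  out <- list(upper = NULL, lower = NULL)
  ## upper branch: M_L = 0
  M_Ru <- p$beta[["R"]] * (I_R - p$theta[["R"]])
  if (M_Ru > 0) {
    M_Fu <- p$beta[["F"]] * rectify(I_F + p$gam_FR * M_Ru - p$theta[["F"]])
    lts_drive <- p$k_LR * u * M_Ru - p$gam_LF * M_Fu - p$theta[["L"]]
    if (lts_drive <= 0)
      out$upper <- c(R = M_Ru, L = 0, F = M_Fu)
  }
  ## lower branch: M_F = 0, solve the 2x2 linear system
  if (M_Ru > 0) {
    A <- M_Ru                      # beta_R (I_R - theta_R)
    B <- p$beta[["R"]] * p$gam_RL  # RS loss per unit LTS rate
    denom <- 1 + p$k_LR * u * p$beta[["L"]] * B
    M_Ll <- p$beta[["L"]] * (p$k_LR * u * A - p$theta[["L"]]) / denom
    if (M_Ll > 0) {
      M_Rl <- A - B * M_Ll
      fs_drive <- I_F + p$gam_FR * M_Rl - p$theta[["F"]]
      if (M_Rl > 0 && fs_drive <= 0)
        out$lower <- c(R = M_Rl, L = M_Ll, F = 0)
    }
  }
  out
}

#' Saddle-node values of the frozen facilitation
#'
#' Closed-form end points of the two fast-subsystem branches: `u_plus`, where
#' the upper branch loses existence at LTS onset (`M_L = 0+`, FS rate taken
#' from the upper-branch balance), and `u_minus`, where the lower branch
#' loses existence at FS onset (`M_F = 0+`, the RS rate there being fixed by
#' the FS threshold condition). Both are linear-algebraic; no iteration.
#'
#' @inheritParams fast_branches
#' @return A list with `u_plus`, `u_minus` (`NA` with a reason in `notes`
#'   when an onset condition cannot be met by a valid branch), the
#'   upper-branch rate `M_R_upper`, and `M_R_fs_onset` (RS rate at FS onset).
#' @export
saddle_points <- function(spec, I_R, I_F) {
  p <- reduced_params(spec)
  notes <- character(0)
  M_Ru <- p$beta[["R"]] * (I_R - p$theta[["R"]])
  if (M_Ru <= 0)
    return(list(u_plus = NA_real_, u_minus = NA_real_, M_R_upper = 0,
                M_R_fs_onset = NA_real_, notes = "RS silent"))
  ## u+ : LTS onset on the upper branch
  M_Fu <- p$beta[["F"]] * rectify(I_F + p$gam_FR * M_Ru - p$theta[["F"]])
  u_plus <- (p$theta[["L"]] + p$gam_LF * M_Fu) / (p$k_LR * M_Ru)
  ## u- : FS onset on the lower branch; RS rate pinned by the FS threshold
  M_Rfs <- (p$theta[["F"]] - I_F) / p$gam_FR
  u_minus <- NA_real_
  if (M_Rfs <= 0) {
    notes <- c(notes, "FS active at any RS rate (I_F >= theta_F)")
  } else if (M_Rfs >= M_Ru) {
    notes <- c(notes, "FS onset requires RS rate above the free-RS rate")
  } else {
    B <- p$beta[["R"]] * p$gam_RL
    M_Lfs <- (M_Ru - M_Rfs) / B
    u_minus <- (M_Lfs / p$beta[["L"]] + p$theta[["L"]]) / (p$k_LR * M_Rfs)
  }
  list(u_plus = u_plus, u_minus = u_minus, M_R_upper = M_Ru,
       M_R_fs_onset = M_Rfs, notes = notes)
}

#' Oscillation conditions of the fast-slow reduction
#'
#' Evaluates the three conditions that are jointly necessary and sufficient
#' for slow relaxation oscillations of the reduced circuit:
#' (i) fast-subsystem bistability, `u_plus > u_minus`;
#' (ii) the slow nullcline clears the upper branch — the nullcline value at
#' the upper-branch rate lies beyond `u_plus`, so `u` keeps growing there;
#' (iii) the nullcline clears the lower branch over `[u_minus, u_plus]` — the
#' lower branch's RS rate is largest at `u_minus`, so it suffices that
#' `u_minus` exceeds the nullcline value at the FS-onset rate, and `u` keeps
#' shrinking along the branch. The predicted regime label follows from which
#' branch (if any) retains a fixed point.
#'
#' @inheritParams fast_branches
#' @return An object of class `fast_slow_result`: `C`, `u_plus`, `u_minus`,
#'   `M_R_upper`, the three logical flags `bistable`, `upper_no_intersect`,
#'   `lower_no_intersect`, `oscillation` (all three true) and the predicted
#'   regime `label`.
#' @export
oscillation_conditions <- function(spec, I_R, I_F) {
  p <- reduced_params(spec)
  sp <- saddle_points(spec, I_R, I_F)
  res <- list(C = p$C, u_plus = sp$u_plus, u_minus = sp$u_minus,
              M_R_upper = sp$M_R_upper, M_R_fs_onset = sp$M_R_fs_onset,
              bistable = FALSE, upper_no_intersect = FALSE,
              lower_no_intersect = FALSE, oscillation = FALSE,
              label = NA_character_)
  class(res) <- "fast_slow_result"
  if (sp$M_R_upper <= 0) { res$label <- "MR=0"; return(res) }

  null_up <- slow_nullcline(p$C, sp$M_R_upper)
  res$upper_no_intersect <- is.finite(sp$u_plus) && null_up > sp$u_plus
  # the lower branch never terminates when FS cannot fire on it (their
  # threshold rate exceeds the free-RS rate); it is absent when I_F alone
  # already drives FS
  lower_unbounded <- is.finite(sp$M_R_fs_onset) && sp$M_R_fs_onset >= sp$M_R_upper
  res$lower_no_intersect <- is.finite(sp$u_minus) && is.finite(sp$M_R_fs_onset) &&
    sp$M_R_fs_onset > 0 && sp$u_minus > slow_nullcline(p$C, sp$M_R_fs_onset)
  res$bistable <- is.finite(sp$u_plus) && is.finite(sp$u_minus) &&
    sp$u_plus > sp$u_minus
  res$oscillation <- res$bistable && res$upper_no_intersect &&
    res$lower_no_intersect
  if (res$oscillation) { res$label <- "osc"; return(res) }

  ## otherwise locate the resting state
  M_Fu <- p$beta[["F"]] * rectify(I_F + p$gam_FR * sp$M_R_upper - p$theta[["F"]])
  upper_fp <- !res$upper_no_intersect   # nullcline meets the upper branch
  if (upper_fp) {
    res$label <- if (M_Fu > 0) "ML=0" else "ML=MF=0"
  } else if (lower_unbounded || (is.finite(sp$u_minus) &&
                                 !res$lower_no_intersect)) {
    res$label <- "MF=0"
  } else {
    # lower branch absent (FS driven above threshold by I_F alone) or
    # bistability lost: the remaining equilibrium has both interneuron
    # populations active
    res$label <- "ML>0,MF>0"
  }
  res
}

#' @export
print.fast_slow_result <- function(x, ...) {
  cat("Fast-slow reduction (C =", x$C, "ms)\n")
  cat(sprintf("  u+ = %.4f, u- = %.4f, upper-branch M_R = %.4f ms^-1\n",
              x$u_plus, x$u_minus, x$M_R_upper))
  cat(sprintf("  bistable: %s, upper clear: %s, lower clear: %s -> %s\n",
              x$bistable, x$upper_no_intersect, x$lower_no_intersect,
              if (x$oscillation) "oscillation" else x$label))
  invisible(x)
}

#' Phase diagram predicted by the fast-slow reduction
#'
#' Evaluates [oscillation_conditions()] on a grid of constant inputs.
#'
#' @inheritParams fast_branches
#' @param I_R_values,I_F_values grid values (nA).
#' @return A data.frame with `I_R`, `I_F` and the predicted `label`.
#' @export
reduced_phase_diagram <- function(spec, I_R_values, I_F_values) {
  grid <- expand.grid(I_R = I_R_values, I_F = I_F_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$label <- vapply(seq_len(nrow(grid)), function(i)
    oscillation_conditions(spec, grid$I_R[i], grid$I_F[i])$label, "")
  grid
}

#' Width of the oscillatory input band at fixed RS input
#'
#' Measures the extent in `I_F` of the predicted slow-oscillation regime at
#' one `I_R`, by evaluating the closed-form conditions on a fine `I_F` grid.
#'
#' @inheritParams fast_branches
#' @param I_F_range search interval (nA); the band always lies below
#'   `theta_F`.
#' @param resolution `I_F` grid step (nA).
#' @return A list with `width` (nA), `lower`, `upper` (band edges, `NA` when
#'   no oscillatory point exists).
#' @export
oscillatory_band <- function(spec, I_R, I_F_range = NULL,
                             resolution = 2e-4) {
  if (is.null(I_F_range))
    I_F_range <- c(0, spec$populations[["F"]]$theta)
  xs <- seq(I_F_range[1], I_F_range[2], by = resolution)
  osc <- vapply(xs, function(IF_)
    oscillation_conditions(spec, I_R, IF_)$oscillation, TRUE)
  if (!any(osc)) return(list(width = 0, lower = NA_real_, upper = NA_real_))
  list(width = sum(osc) * resolution,
       lower = xs[which(osc)[1]], upper = xs[rev(which(osc))[1]])
}

#' Relaxation-oscillation period from the slow dynamics
#'
#' Approximates the limit-cycle period by integrating the exact facilitation
#' kinetics `du/dt = (U - u)/tau_f + U (1 - u) M_R` along each branch
#' between the saddle-node values: up the upper branch from `u_minus` to
#' `u_plus` at the constant upper rate, then down the lower branch from
#' `u_plus` back to `u_minus` with the u-dependent lower rate. The fast
#' jumps contribute negligibly.
#'
#' @inheritParams fast_branches
#' @return Approximate period (ms); `NA` when the reduction predicts no
#'   oscillation.
#' @export
fast_slow_period <- function(spec, I_R, I_F) {
  oc <- oscillation_conditions(spec, I_R, I_F)
  if (!isTRUE(oc$oscillation)) return(NA_real_)
  p <- reduced_params(spec)
  dudt <- function(u, M) (p$U_LR - u) / p$tau_f_LR + p$U_LR * (1 - u) * M
  t_up <- stats::integrate(function(u)
    1 / dudt(u, oc$M_R_upper), oc$u_minus, oc$u_plus,
    rel.tol = 1e-8)$value
  lower_rate <- function(u) vapply(u, function(ui)
    fast_branches(spec, I_R, I_F, ui)$lower[["R"]], numeric(1))
  t_down <- stats::integrate(function(u)
    1 / dudt(u, lower_rate(u)), oc$u_plus, oc$u_minus,
    rel.tol = 1e-8)$value
  t_up + t_down
}
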