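# Attractor classification and oscillation metrics on simulated trajectories.
#
# Thresholds: a population counts as active when its mean rate exceeds
# EPS_M = 1e-5 ms^-1 (0.01 Hz); a trajectory counts as oscillatory when the
# peak-to-trough amplitude of the RS rate in the analysis window exceeds
# EPS_OSC = 1e-4 ms^-1. Both sit far below modelled rates (~1e-3..1e-1 ms^-1)
# and far above the integrator's noise floor.

EPS_M <- 1e-5
EPS_OSC <- 1e-4

window_index <- function(traj, transient, window) {
  t_max <- max(traj$time)
  if (t_max < transient + window)
    stop("trajectory shorter than transient + window")
  which(traj$time > t_max - window)
}

#' Classify the long-time attractor of a trajectory
#'
#' Discards a transient, then labels the trajectory `"rest"` or
#' `"oscillatory"` from the peak-to-trough amplitude of the RS rate in the
#' analysis window. Populations are `active` when their mean rate exceeds
#' 1e-5 ms^-1. For oscillatory trajectories the frequency and the
#' more-active-state duty cycle are measured (see
#' [oscillation_frequency_and_duty()]); oscillations are tagged `"slow"`
#' below 15 Hz and `"fast"` above (the two families the circuit produces sit
#' near 1-10 Hz and 20-60 Hz).
#'
#' @param traj a `trajectory` from [simulate_circuit()].
#' @param transient initial time to discard (ms).
#' @param window analysis window at the end of the trajectory (ms).
#' @return A list of class `attractor_report` with `kind`, `active`,
#'   `rates` (window means), `min`, `max`, and for oscillatory trajectories
#'   `frequency` (Hz), `duty` and `band` (`"slow"`/`"fast"`).
#' @export
classify_attractor <- function(traj, transient = 5000, window = 5000) {
  ii <- window_index(traj, transient, window)
  R <- traj$rates[ii, , drop = FALSE]
  means <- colMeans(R)
  amp <- max(R[, "R"]) - min(R[, "R"])
  kind <- if (amp > EPS_OSC) "oscillatory" else "rest"
  rep <- list(kind = kind,
              active = names(means)[means > EPS_M],
              rates = means,
              min = apply(R, 2, min), max = apply(R, 2, max),
              frequency = NA_real_, duty = NA_real_, band = NA_character_)
  if (kind == "oscillatory") {
    # FS activity marks the RS more-active state; when FS stay silent (e.g.
    # fast recurrent-excitation oscillations) fall back to the RS median
    fd <- tryCatch(oscillation_frequency_and_duty(traj, transient, window),
                   error = function(e)
                     oscillation_frequency_and_duty(traj, transient, window,
                                                    marker = "R-median"))
    rep$frequency <- fd$frequency
    rep$duty <- fd$duty
    rep$band <- if (fd$frequency < 15) "slow" else "fast"
  }
  structure(rep, class = "attractor_report")
}

#' @export
print.attractor_report <- function(x, ...) {
  cat("Attractor:", x$kind,
      if (x$kind == "oscillatory")
        sprintf("(%s, %.2f Hz, duty %.2f)", x$band, x$frequency, x$duty)
      else "", "\n")
  cat("Active populations:",
      if (length(x$active)) paste(x$active, collapse = ", ") else "none", "\n")
  cat("Mean rates (Hz):",
      paste(sprintf("%s = %.3f", names(x$rates), 1000 * x$rates),
            collapse = ", "), "\n")
  invisible(x)
}

upward_crossings <- function(t, y, level) {
  below <- y[-length(y)] <= level & y[-1] > level
  i <- which(below)
  if (!length(i)) return(numeric(0))
  # linear interpolation of the crossing time
  t[i] + (level - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i])
}

#' Frequency and duty cycle of the slow oscillation
#'
#' The RS more-active state is marked by FS activity: the period is measured
#' from upward crossings of the FS rate through the activity threshold, and
#' the duty cycle is the fraction of the (whole-cycle) span with the FS rate
#' above threshold. A cross-check marker based on the RS rate crossing its
#' window median is available and agrees within one sample on clean limit
#' cycles.
#'
#' @inheritParams classify_attractor
#' @param marker `"F"` (FS activity marks the more-active state) or
#'   `"R-median"` (RS rate above its median).
#' @return A list with `frequency` (Hz), `duty` (fraction) and the crossing
#'   times (ms).
#' @export
oscillation_frequency_and_duty <- function(traj, transient = 5000,
                                           window = 5000,
                                           marker = c("F", "R-median")) {
  marker <- match.arg(marker)
  ii <- window_index(traj, transient, window)
  t <- traj$time[ii]
  y <- switch(marker, "F" = traj$rates[ii, "F"], "R-median" = traj$rates[ii, "R"])
  level <- switch(marker, "F" = EPS_M,
                  "R-median" = stats::median(traj$rates[ii, "R"]))
  cross <- upward_crossings(t, y, level)
  if (length(cross) < 3)
    stop("insufficient cycles: fewer than 3 upward crossings in window")
  span <- cross[length(cross)] - cross[1]
  period <- span / (length(cross) - 1)
  sel <- t >= cross[1] & t < cross[length(cross)]
  duty <- mean(y[sel] > level)
  list(frequency = 1000 / period, duty = duty, crossings = cross,
       period = period)
}

#' Cycle-averaged rates under periodic (or constant) stimulation
#'
#' Time-averaged rates `<M> = (1/T) integral M dt` over the final
#' `n_cycles` stimulus cycles after the system has converged to its
#' attractor. For a constant-input protocol the average equals the rest
#' rate and the integration window is `n_cycles * 1000/3` ms.
#'
#' @param traj a `trajectory` driven by a square-wave or constant protocol.
#' @param n_cycles number of stimulus cycles to integrate over.
#' @param transient time to discard before averaging (ms).
#' @return Named vector of time-averaged rates (ms^-1).
#' @export
cycle_averaged_rates <- function(traj, n_cycles = 10, transient = 3000) {
  kinds <- vapply(traj$protocol, `[[`, "", "kind")
  if (any(kinds == "step"))
    stop("cycle averaging requires a periodic (or constant) protocol")
  period <- if (any(kinds == "square"))
    1000 / traj$protocol[[which(kinds == "square")[1]]]$freq
  else 1000 / 3
  T_integ <- n_cycles * period
  t_max <- max(traj$time)
  if (t_max < transient + T_integ)
    stop("trajectory shorter than transient + integration time")
  ii <- traj$time > t_max - T_integ
  colMeans(traj$rates[ii, , drop = FALSE])
}

#' Measure the LTS recruitment delay from a step-response trajectory
#'
#' First time the LTS rate exceeds the activity threshold (1e-5 ms^-1) after
#' the step onset, minus the onset time; `Inf` when LTS neurons never fire in
#' the trace.
#'
#' @param traj a `trajectory` under a step protocol with LTS initially silent.
#' @return Delay (ms) or `Inf`.
#' @export
measure_lts_delay <- function(traj) {
  onset <- 0
  for (w in traj$protocol) if (w$kind == "step") onset <- w$onset
  t <- traj$time
  y <- traj$rates[, "L"]
  sel <- t >= onset
  cross <- upward_crossings(t[sel], y[sel], EPS_M)
  if (!length(cross)) return(Inf)
  cross[1] - onset
}
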