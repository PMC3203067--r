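#' Simulate a circuit with fixed-step RK4
#'
#' Integrates the synaptic/adaptation state with the classic fourth-order
#' Runge-Kutta scheme at a fixed time step (default 0.02 ms); population
#' rates are recomputed algebraically at every stage evaluation. The default
#' initial state is the long-rested network (`s = 0`, `x = 1`, `u = U`,
#' `a = 0`).
#'
#' @param spec a [circuit_spec()].
#' @param proto a [protocol()]; populations not mentioned receive zero input.
#' @param t_end simulation length (ms), positive.
#' @param dt integration step (ms), default 0.02.
#' @param init optional `network_state` initial condition.
#' @param record_dt output sampling interval (ms); must be a multiple of
#'   `dt`. Defaults to `dt` for short runs and 0.1 ms when
#'   `t_end > 2000` ms to keep trajectories light.
#' @return An object of class `trajectory`: list with `time` (ms), `rates`
#'   (matrix, ms^-1, one column per population), `s`, `x`, `u` (one column
#'   per synapse), `a`, plus the `spec`, `protocol` and `dt` that produced it.
#' @export
#' @examples
#' spec <- reference_circuit()
#' tr <- simulate_circuit(spec, protocol(R = stim_step(0.3)), t_end = 500)
#' max(tr$rates[, "R"])
simulate_circuit <- function(spec, proto = protocol(), t_end, dt = 0.02,
                             init = NULL, record_dt = NULL) {
  stopifnot(inherits(spec, "circuit_spec"), inherits(proto, "stimulus_protocol"),
            t_end > 0, dt > 0)
  if (is.null(record_dt)) record_dt <- if (t_end > 2000) 0.1 else dt
  keep <- max(1L, as.integer(round(record_dt / dt)))
  if (abs(keep * dt - record_dt) > 1e-9)
    stop("record_dt must be an integer multiple of dt")
  if (is.null(init)) init <- default_state(spec)
  validate_state(spec, init)

  labels <- pop_labels(spec)
  syn_names <- names(spec$synapses)
  pre_idx <- match(syn_char(spec, "pre"), labels) - 1L
  post_idx <- match(syn_char(spec, "post"), labels) - 1L
  adapt <- as.integer(vapply(spec$populations, `[[`, TRUE, "adapt"))

  y0 <- c(init$s, init$x, init$u, init$a)
  out <- .sim_rk4(pre_idx, post_idx,
                  syn_field(spec, "g"), syn_field(spec, "U"),
                  syn_field(spec, "tau_s"), syn_field(spec, "tau_f"),
                  syn_field(spec, "tau_r"), syn_field(spec, "sign"),
                  pop_field(spec, "theta"), pop_field(spec, "beta_tilde"),
                  adapt, pop_field(spec, "tau_a"), pop_field(spec, "gbar_a"),
                  protocol_matrix(proto, labels), y0,
                  t_end, dt, keep)

  colnames(out$rates) <- colnames(out$a) <- labels
  colnames(out$s) <- colnames(out$x) <- colnames(out$u) <- syn_names
  structure(list(time = out$time, rates = out$rates, s = out$s, x = out$x,
                 u = out$u, a = out$a, spec = spec, protocol = proto,
                 dt = dt, record_dt = keep * dt),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$time), "samples over", max(x$time), "ms",
      sprintf("(dt = %g ms, recorded every %g ms)\n", x$dt, x$record_dt))
  fin <- x$rates[nrow(x$rates), ]
  cat("Final rates (Hz):",
      paste(sprintf("%s = %.2f", colnames(x$rates), 1000 * fin),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.trajectory <- function(x, which = colnames(x$rates), hz = TRUE, ...) {
  y <- x$rates[, which, drop = FALSE]
  if (hz) y <- 1000 * y
  graphics::matplot(x$time, y, type = "l", lty = 1,
                    xlab = "time (ms)",
                    ylab = if (hz) "rate (Hz)" else "rate (1/ms)", ...)
  graphics::legend("topright", legend = which, col = seq_along(which),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Extract the state at one trajectory sample
#'
#' @param traj a `trajectory`.
#' @param t time (ms); the nearest recorded sample is used.
#' @return A `network_state`.
#' @export
state_at <- function(traj, t = max(traj$time)) {
  i <- which.min(abs(traj$time - t))
  structure(list(s = traj$s[i, ], x = traj$x[i, ], u = traj$u[i, ],
                 a = traj$a[i, ]), class = "network_state")
}

#' Write a trajectory to delimited text
#'
#' Writes a tab-separated table with a `time_ms` column, the per-population
#' rates (ms^-1) and the synaptic/adaptation state series.
#'
#' @param traj a `trajectory`.
#' @param path output file path.
#' @export
write_trajectory <- function(traj, path) {
  tab <- data.frame(time_ms = traj$time, check.names = FALSE)
  for (p in colnames(traj$rates)) tab[[paste0("M_", p)]] <- traj$rates[, p]
  for (k in colnames(traj$s)) {
    key <- gsub("<-", "_", k, fixed = TRUE)
    tab[[paste0("s_", key)]] <- traj$s[, k]
    tab[[paste0("x_", key)]] <- traj$x[, k]
    tab[[paste0("u_", key)]] <- traj$u[, k]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
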