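#' Rectification (linear-threshold) transfer function
#'
#' The population transfer function is linear above zero and zero below:
#' `rectify(v)` returns `v` for `v >= 0` and `0` otherwise. Population firing
#' rates are `beta * rectify(total input - threshold)`.
#'
#' @param v numeric vector of current-like values (nA).
#' @return Numeric vector, `pmax(v, 0)`.
#' @export
#' @examples
#' rectify(c(-0.3, 0, 0.3))
rectify <- function(v) {
  stopifnot(is.numeric(v), all(is.finite(v)))
  pmax(v, 0)
}

POP_LABELS <- c("R", "L", "F")

#' Population parameters
#'
#' Describes one neuronal population of the rate model: a firing threshold
#' `theta` (nA) and a steady-state gain `beta` (ms^-1 nA^-1), so that at rest
#' the rate is `beta * [I - theta]+`. An optional spike-frequency adaptation
#' current can be attached; its strength `gbar_a` (nA per unit rate) and time
#' constant `tau_a` (ms) define an adaptation variable `a` with
#' `da/dt = (-a + gbar_a * M) / tau_a`. When adaptation is present the
#' instantaneous gain is `beta_tilde = beta / (1 - beta * gbar_a)`, chosen so
#' that the steady-state gain `beta_tilde / (1 + beta_tilde * gbar_a)` equals
#' `beta` (matched-gain constraint): the steady-state rate-current curve is
#' identical with and without adaptation, only the transient differs.
#'
#' @param label population identifier, one of `"R"` (regular-spiking,
#'   excitatory), `"L"` (low-threshold-spiking interneurons) or `"F"`
#'   (fast-spiking interneurons).
#' @param theta firing threshold (nA).
#' @param beta steady-state gain (ms^-1 nA^-1), must be positive.
#' @param tau_a adaptation time constant (ms); `NA` disables adaptation.
#' @param gbar_a adaptation strength (nA per ms^-1 of rate); requires
#'   `beta * gbar_a < 1` so the matched instantaneous gain exists.
#' @return A list of class `population_params`.
#' @export
population <- function(label, theta, beta, tau_a = NA_real_, gbar_a = 0) {
  label <- match.arg(label, POP_LABELS)
  stopifnot(is.finite(theta), is.finite(beta), beta > 0, gbar_a >= 0)
  has_adapt <- is.finite(tau_a) && gbar_a > 0
  if (has_adapt) {
    stopifnot(tau_a > 0)
    if (beta * gbar_a >= 1)
      stop("adaptation too strong: need beta * gbar_a < 1 for matched gain")
    beta_tilde <- beta / (1 - beta * gbar_a)
  } else {
    tau_a <- 0
    gbar_a <- 0
    beta_tilde <- beta
  }
  structure(list(label = label, theta = theta, beta = beta,
                 adapt = has_adapt, tau_a = tau_a, gbar_a = gbar_a,
                 beta_tilde = beta_tilde),
            class = "population_params")
}

#' Synapse parameters with short-term plasticity
#'
#' One directed connection (`post <- pre`) following Tsodyks-Markram kinetics.
#' Three dynamic variables are attached to every synapse: the open-channel
#' fraction `s` (decay `tau_s`), the available-resource fraction `x`
#' (depression, recovery `tau_r`) and the running utilization `u`
#' (facilitation, recovery `tau_f`, baseline `U`). `tau_r = 0` pins `x` at 1
#' (no depression) and `tau_f = 0` pins `u` at `U` (no facilitation); these
#' are exact algebraic pins, not small time constants. The synaptic current
#' into the postsynaptic population is `sign * g * s`, with `sign = +1` for an
#' excitatory (RS) presynaptic population and `-1` for inhibitory (LTS, FS).
#'
#' @param pre,post population labels (`"R"`, `"L"` or `"F"`).
#' @param g synaptic efficacy coefficient (arbitrary units; `g * s` is nA).
#' @param U baseline release probability, in (0, 1].
#' @param tau_s postsynaptic current decay time (ms), positive.
#' @param tau_f facilitation recovery time (ms); 0 means no facilitation.
#' @param tau_r depression recovery time (ms); 0 means no depression.
#' @return A list of class `synapse_params`.
#' @export
synapse <- function(pre, post, g, U, tau_s, tau_f = 0, tau_r = 0) {
  pre <- match.arg(pre, POP_LABELS)
  post <- match.arg(post, POP_LABELS)
  stopifnot(g >= 0, U > 0, U <= 1, tau_s > 0, tau_f >= 0, tau_r >= 0)
  structure(list(pre = pre, post = post, g = g, U = U,
                 tau_s = tau_s, tau_f = tau_f, tau_r = tau_r,
                 sign = if (pre == "R") 1 else -1),
            class = "synapse_params")
}

#' Circuit specification
#'
#' Bundles populations and directed synapses into one network description.
#' At most one synapse per ordered (post <- pre) pair is allowed, and every
#' synapse endpoint must name a declared population. An absent pair means no
#' connection.
#'
#' @param populations a list of [population()] objects.
#' @param synapses a list of [synapse()] objects (possibly empty).
#' @return An object of class `circuit_spec` with components
#'   `populations` (named list) and `synapses` (list; names `"post<-pre"`).
#' @seealso [reference_circuit()], [reduced_circuit()]
#' @export
circuit_spec <- function(populations, synapses = list()) {
  stopifnot(all(vapply(populations, inherits, TRUE, "population_params")),
            all(vapply(synapses, inherits, TRUE, "synapse_params")))
  labels <- vapply(populations, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate population labels")
  names(populations) <- labels
  syn_names <- vapply(synapses, function(s) paste0(s$post, "<-", s$pre), "")
  if (anyDuplicated(syn_names)) stop("duplicate synapse for an ordered pair")
  for (s in synapses)
    if (!(s$pre %in% labels) || !(s$post %in% labels))
      stop("synapse endpoint names an undeclared population: ", s$pre, "->", s$post)
  names(synapses) <- syn_names
  structure(list(populations = populations, synapses = synapses),
            class = "circuit_spec")
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat("Rate-model circuit:", length(x$populations), "population(s),",
      length(x$synapses), "synapse(s)\n")
  pd <- do.call(rbind, lapply(x$populations, function(p)
    data.frame(label = p$label, theta_nA = p$theta, beta = p$beta,
               adaptation = p$adapt)))
  print(pd, row.names = FALSE)
  if (length(x$synapses)) {
    sd <- do.call(rbind, lapply(x$synapses, function(s)
      data.frame(connection = paste0(s$post, "<-", s$pre), g = s$g, U = s$U,
                 tau_s = s$tau_s, tau_f = s$tau_f, tau_r = s$tau_r,
                 sign = s$sign)))
    print(sd, row.names = FALSE)
  }
  invisible(x)
}

pop_labels <- function(spec) names(spec$populations)

pop_field <- function(spec, field)
  vapply(spec$populations, `[[`, numeric(1), field)

syn_field <- function(spec, field)
  vapply(spec$synapses, `[[`, numeric(1), field)

syn_char <- function(spec, field)
  vapply(spec$synapses, `[[`, character(1), field)

#' Reference RS-LTS-FS cortical circuit
#'
#' Builds the full three-population circuit with the reference parameter set:
#' RS threshold 0.1 nA and gain 0.11, LTS 0.05/0.32, FS 0.28/0.35, and eight
#' synapses (there is no LTS-to-LTS chemical connection). The RS-to-LTS
#' synapse facilitates (tau_f = 670 ms, U = 0.09) and all other connections
#' depress.
#'
#' @param g_RR logical; include the recurrent RS-to-RS synapse (efficacy 5)?
#'   `FALSE` sets its efficacy to 0.
#' @param adaptation logical; attach spike-frequency adaptation currents to
#'   every population (matched-gain construction, see [population()]).
#' @param gbar_a named numeric adaptation strengths for `R`, `L`, `F` (nA per
#'   ms^-1), used when `adaptation = TRUE`. The strengths are deliberately a
#'   configuration knob; defaults give a moderate transient boost.
#' @param tau_a named adaptation time constants (ms).
#' @return A [circuit_spec()].
#' @export
#' @examples
#' spec <- reference_circuit()
#' length(spec$synapses) # 8
reference_circuit <- function(g_RR = TRUE, adaptation = FALSE,
                              gbar_a = c(R = 2, L = 1, F = 1),
                              tau_a = c(R = 100, L = 100, F = 100)) {
  pops <- list(
    population("R", theta = 0.10, beta = 0.11,
               tau_a = if (adaptation) tau_a[["R"]] else NA,
               gbar_a = if (adaptation) gbar_a[["R"]] else 0),
    population("L", theta = 0.05, beta = 0.32,
               tau_a = if (adaptation) tau_a[["L"]] else NA,
               gbar_a = if (adaptation) gbar_a[["L"]] else 0),
    population("F", theta = 0.28, beta = 0.35,
               tau_a = if (adaptation) tau_a[["F"]] else NA,
               gbar_a = if (adaptation) gbar_a[["F"]] else 0))
  syns <- list(
    synapse("R", "R", g = if (g_RR) 5 else 0, U = 0.21, tau_s = 2,   tau_r = 463),
    synapse("L", "R", g = 35, U = 0.30, tau_s = 6.3, tau_r = 1250),
    synapse("R", "L", g = 7,  U = 0.09, tau_s = 2,   tau_f = 670),
    synapse("F", "R", g = 38, U = 0.14, tau_s = 2,   tau_r = 875),
    synapse("R", "F", g = 18, U = 0.30, tau_s = 2,   tau_r = 227),
    synapse("L", "F", g = 5,  U = 0.30, tau_s = 2,   tau_r = 400),
    synapse("F", "L", g = 10, U = 0.30, tau_s = 2,   tau_r = 400),
    synapse("F", "F", g = 20, U = 0.30, tau_s = 2,   tau_r = 400))
  circuit_spec(pops, syns)
}

#' Reduced RS-LTS-FS circuit for fast-slow analysis
#'
#' The minimal circuit that still produces the facilitation-driven slow
#' oscillation: only the RS-to-LTS, LTS-to-RS, RS-to-FS and FS-to-LTS
#' connections are kept and all depression is removed (`tau_r = 0`
#' everywhere), so the facilitation variable of the RS-to-LTS synapse is the
#' only slow variable. Efficacies: g(L<-R) = 7.5, g(F<-R) = 9.3,
#' g(L<-F) = 8, g(R<-L) = 35; other kinetic constants as in the reference
#' circuit.
#'
#' @return A [circuit_spec()] with four synapses.
#' @export
reduced_circuit <- function() {
  pops <- list(population("R", 0.10, 0.11),
               population("L", 0.05, 0.32),
               population("F", 0.28, 0.35))
  syns <- list(
    synapse("R", "L", g = 7.5, U = 0.09, tau_s = 2,   tau_f = 670),
    synapse("L", "R", g = 35,  U = 0.30, tau_s = 6.3),
    synapse("R", "F", g = 9.3, U = 0.30, tau_s = 2),
    synapse("F", "L", g = 8,   U = 0.30, tau_s = 2))
  circuit_spec(pops, syns)
}

#' Default (rested) network state
#'
#' The long-rested initial condition: all synaptic channels closed (`s = 0`),
#' full vesicle availability (`x = 1`), utilization at baseline (`u = U`) and
#' no adaptation current (`a = 0`).
#'
#' @param spec a [circuit_spec()].
#' @return A list of class `network_state` with named vectors `s`, `x`, `u`
#'   (one entry per synapse) and `a` (one per population).
#' @export
default_state <- function(spec) {
  ns <- length(spec$synapses)
  sn <- names(spec$synapses)
  st <- list(s = stats::setNames(rep(0, ns), sn),
             x = stats::setNames(rep(1, ns), sn),
             u = stats::setNames(syn_field(spec, "U"), sn),
             a = stats::setNames(rep(0, length(spec$populations)),
                                 pop_labels(spec)))
  structure(st, class = "network_state")
}

validate_state <- function(spec, state) {
  stopifnot(length(state$s) == length(spec$synapses),
            length(state$x) == length(spec$synapses),
            length(state$u) == length(spec$synapses),
            length(state$a) == length(spec$populations))
  if (any(state$s < 0) || any(state$x < 0) || any(state$u < 0) ||
      any(state$a < 0))
    stop("negative state components")
  invisible(TRUE)
}

#' Algebraic population rates
#'
#' Rates are purely algebraic in the synaptic state: for population i,
#' `M_i = beta_i * [I_i + sum_j sign_ij g_ij s_ij - a_i - theta_i]+`
#' (with `beta_tilde` in place of `beta` when adaptation is attached; the
#' adaptation current `a_i` is subtracted from the drive).
#'
#' @param spec a [circuit_spec()].
#' @param state a `network_state` (see [default_state()]).
#' @param inputs named numeric vector of external inputs (nA) per population;
#'   omitted populations receive 0.
#' @return Named numeric vector of rates (ms^-1).
#' @export
population_rates <- function(spec, state, inputs = NULL) {
  labels <- pop_labels(spec)
  I <- stats::setNames(rep(0, length(labels)), labels)
  if (!is.null(inputs)) {
    if (length(inputs) && is.null(names(inputs)))
      stop("inputs must be a named vector")
    unknown <- setdiff(names(inputs), labels)
    if (length(unknown))
      stop("unknown population label in inputs: ", paste(unknown, collapse = ", "))
    I[names(inputs)] <- inputs
  }
  drive <- I
  for (k in seq_along(spec$synapses)) {
    syn <- spec$synapses[[k]]
    drive[syn$post] <- drive[syn$post] + syn$sign * syn$g * state$s[[k]]
  }
  drive <- drive - state$a - pop_field(spec, "theta")
  pop_field(spec, "beta_tilde") * rectify(drive)
}

#' Time derivatives of the network state
#'
#' Tsodyks-Markram kinetics driven by the presynaptic rates: per synapse
#' (post i <- pre j) `ds/dt = -s/tau_s + u x M_j`,
#' `dx/dt = (1-x)/tau_r - u x M_j` (x held at 1 when `tau_r = 0`), and
#' `du/dt = (U-u)/tau_f + U (1-u) M_j` (u held at U when `tau_f = 0`);
#' per population `da/dt = (-a + gbar_a M_i)/tau_a` when adaptation is
#' attached.
#'
#' @param spec a [circuit_spec()].
#' @param state a `network_state`.
#' @param rates named rate vector as returned by [population_rates()] for the
#'   same state.
#' @return A list with the same shape as the state (`s`, `x`, `u`, `a`).
#' @export
state_derivatives <- function(spec, state, rates) {
  validate_state(spec, state)
  ds <- dx <- du <- numeric(length(spec$synapses))
  for (k in seq_along(spec$synapses)) {
    syn <- spec$synapses[[k]]
    Mj <- rates[[syn$pre]]
    rel <- state$u[[k]] * state$x[[k]] * Mj
    ds[k] <- -state$s[[k]] / syn$tau_s + rel
    dx[k] <- if (syn$tau_r > 0) (1 - state$x[[k]]) / syn$tau_r - rel else 0
    du[k] <- if (syn$tau_f > 0)
      (syn$U - state$u[[k]]) / syn$tau_f + syn$U * (1 - state$u[[k]]) * Mj
    else 0
  }
  da <- vapply(seq_along(spec$populations), function(i) {
    p <- spec$populations[[i]]
    if (p$adapt) (-state$a[[i]] + p$gbar_a * rates[[p$label]]) / p$tau_a else 0
  }, numeric(1))
  list(s = stats::setNames(ds, names(state$s)),
       x = stats::setNames(dx, names(state$x)),
       u = stats::setNames(du, names(state$u)),
       a = stats::setNames(da, names(state$a)))
}

#' Steady-state plasticity variables at a constant presynaptic rate
#'
#' Closed forms for the Tsodyks-Markram variables at constant rate `M`:
#' `u* = U (1 + tau_f M) / (1 + U tau_f M)` and
#' `x* = 1 / (1 + tau_r u* M)`; the open fraction then settles at
#' `s* = tau_s u* x* M`.
#'
#' @param syn a [synapse()] object.
#' @param M constant presynaptic rate (ms^-1), vectorised.
#' @return A list with numeric components `u`, `x`, `s`.
#' @export
synapse_steady_state <- function(syn, M) {
  u <- if (syn$tau_f > 0)
    syn$U * (1 + syn$tau_f * M) / (1 + syn$U * syn$tau_f * M)
  else rep(syn$U, length(M))
  x <- if (syn$tau_r > 0) 1 / (1 + syn$tau_r * u * M) else rep(1, length(M))
  list(u = u, x = x, s = syn$tau_s * u * x * M)
}
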