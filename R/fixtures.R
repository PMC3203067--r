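# Deterministic synthetic fixtures for tests of the metrics and property
# suites. All randomness is confined here and controlled by an explicit seed;
# the model itself is deterministic.

#' Synthetic square-labelled trajectory
#'
#' Builds a trajectory-shaped object whose RS rate alternates between two
#' positive levels with an exactly known period and active-phase duration,
#' with the FS rate positive exactly during the RS more-active phase and the
#' LTS rate positive in the complementary phase. Used as an exact oracle for
#' the frequency/duty estimators.
#'
#' @param period oscillation period (ms).
#' @param active duration of the more-active phase per period (ms).
#' @param t_end trace length (ms).
#' @param dt sample spacing (ms).
#' @param high,low RS rates in the two phases (ms^-1), both positive.
#' @return A `trajectory`-classed object with `time` and `rates`.
#' @export
fixture_square_trace <- function(period = 200, active = 60, t_end = 3000,
                                 dt = 0.5, high = 0.03, low = 0.005) {
  stopifnot(active > 0, active < period)
  t <- seq(0, t_end, by = dt)
  phase <- t %% period
  on <- phase < active
  rates <- cbind(R = ifelse(on, high, low),
                 L = ifelse(on, 0, 0.01),
                 F = ifelse(on, 0.02, 0))
  structure(list(time = t, rates = rates,
                 s = matrix(0, length(t), 0), x = matrix(0, length(t), 0),
                 u = matrix(0, length(t), 0),
                 a = matrix(0, length(t), 3, dimnames = list(NULL, c("R", "L", "F"))),
                 spec = NULL, protocol = protocol(), dt = dt,
                 record_dt = dt),
            class = "trajectory")
}

#' Randomised circuit near the reference parameter set
#'
#' Perturbs every synaptic efficacy of the reference circuit by a uniform
#' relative amount (default +-10%), deterministically for a given seed.
#'
#' @param seed integer seed.
#' @param rel maximal relative perturbation.
#' @param ... forwarded to [reference_circuit()].
#' @return A [circuit_spec()].
#' @export
fixture_random_circuit <- function(seed = 1, rel = 0.1, ...) {
  spec <- reference_circuit(...)
  set.seed(seed)
  for (nm in names(spec$synapses)) {
    g <- spec$synapses[[nm]]$g
    spec <- set_synapse(spec, nm, g = g * stats::runif(1, 1 - rel, 1 + rel))
  }
  spec
}

#' Rest-state trajectory fixture
#'
#' A short constant-input simulation of a decoupled RS population, which
#' settles immediately at its rectified-linear rate; classified as rest.
#'
#' @param I_R constant input (nA).
#' @return A `trajectory`.
#' @export
fixture_rest_trace <- function(I_R = 0.5) {
  spec <- circuit_spec(list(population("R", 0.1, 0.11),
                            population("L", 0.05, 0.32),
                            population("F", 0.28, 0.35)))
  simulate_circuit(spec, protocol(R = stim_constant(I_R)), t_end = 4000,
                   dt = 0.02, record_dt = 1)
}
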