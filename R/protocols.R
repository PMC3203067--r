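#' Stimulus waveforms
#'
#' Waveform constructors for per-population external input currents.
#' `stim_constant(amp)` is a constant current; `stim_step(amp, onset)` is zero
#' before `onset` (ms) and `amp` after; `stim_square(mean, freq, duty)` is a
#' periodic square wave that mimics absence-seizure-like thalamic drive: the
#' amplitude during the active phase is `mean / duty`, so the time-averaged
#' current stays at `mean` whatever the duty cycle. The default square-wave
#' frequency is 3 Hz.
#'
#' @param amp,mean current amplitudes (nA).
#' @param onset step onset time (ms).
#' @param freq square-wave frequency (Hz), positive.
#' @param duty active-phase fraction, in (0, 1].
#' @return An object of class `stimulus` (callable description; evaluate with
#'   [stim_eval()]).
#' @name stimulus
NULL

#' @rdname stimulus
#' @export
stim_constant <- function(amp) {
  stopifnot(is.finite(amp))
  structure(list(kind = "constant", amp = amp), class = "stimulus")
}

#' @rdname stimulus
#' @export
stim_step <- function(amp, onset = 0) {
  stopifnot(is.finite(amp), is.finite(onset))
  structure(list(kind = "step", amp = amp, onset = onset), class = "stimulus")
}

#' @rdname stimulus
#' @export
stim_square <- function(mean, freq = 3, duty = 0.1) {
  if (!(duty > 0 && duty <= 1)) stop("duty must lie in (0, 1]")
  stopifnot(freq > 0)
  structure(list(kind = "square", mean = mean, freq = freq, duty = duty),
            class = "stimulus")
}

#' Evaluate a stimulus waveform
#'
#' @param stim a `stimulus` object.
#' @param t time (ms), vectorised.
#' @return Current (nA) at each time.
#' @export
stim_eval <- function(stim, t) {
  switch(stim$kind,
    constant = rep(stim$amp, length(t)),
    step = ifelse(t >= stim$onset, stim$amp, 0),
    square = {
      period <- 1000 / stim$freq
      phase <- (t %% period) / period
      ifelse(phase < stim$duty, stim$mean / stim$duty, 0)
    },
    stop("unknown stimulus kind"))
}

#' Stimulus protocol for a circuit
#'
#' Collects one waveform per population; populations not mentioned receive no
#' external input. `make_protocol` is a convenience wrapper building a
#' single-kind protocol from keyword parameters.
#'
#' @param ... named `stimulus` objects (names are population labels), e.g.
#'   `protocol(R = stim_step(0.5), F = stim_constant(0.35))`.
#' @return An object of class `stimulus_protocol`.
#' @export
protocol <- function(...) {
  waves <- list(...)
  if (length(waves)) {
    stopifnot(!is.null(names(waves)), all(nzchar(names(waves))))
    stopifnot(all(vapply(waves, inherits, TRUE, "stimulus")))
    stopifnot(all(names(waves) %in% POP_LABELS))
  }
  structure(waves, class = "stimulus_protocol")
}

#' @rdname protocol
#' @param kind one of `"constant"`, `"step"`, `"square"`.
#' @param population target population label.
#' @param ...params parameters forwarded to the waveform constructor.
#' @export
make_protocol <- function(kind = c("constant", "step", "square"),
                          population = "R", ...) {
  kind <- match.arg(kind)
  w <- switch(kind,
              constant = stim_constant(...),
              step = stim_step(...),
              square = stim_square(...))
  p <- list(w)
  names(p) <- population
  do.call(protocol, p)
}

protocol_matrix <- function(proto, labels) {
  # rows: kind code + three parameters, one column per population
  m <- matrix(0, nrow = 4, ncol = length(labels),
              dimnames = list(c("kind", "p1", "p2", "p3"), labels))
  for (lab in names(proto)) {
    w <- proto[[lab]]
    m[, lab] <- switch(w$kind,
      constant = c(0, w$amp, 0, 0),
      step = c(1, w$amp, w$onset, 0),
      square = c(2, w$mean, w$freq, w$duty))
  }
  m
}

protocol_inputs <- function(proto, labels, t) {
  I <- stats::setNames(rep(0, length(labels)), labels)
  for (lab in names(proto)) I[lab] <- stim_eval(proto[[lab]], t)
  I
}
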