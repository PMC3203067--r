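#' Write and read circuit configuration files
#'
#' Circuits are serialised to a structured key-value text file (YAML) with
#' one block per population and per synapse; the round trip preserves every
#' parameter value exactly (numbers are written with full double precision).
#'
#' @param spec a [circuit_spec()].
#' @param path file path.
#' @return `write_circuit` returns the path invisibly; `read_circuit`
#'   returns the reconstructed [circuit_spec()].
#' @export
write_circuit <- function(spec, path) {
  pops <- lapply(spec$populations, function(p) {
    out <- list(theta = p$theta, beta = p$beta)
    if (p$adapt) {
      out$tau_a <- p$tau_a
      out$gbar_a <- p$gbar_a
    }
    out
  })
  syns <- lapply(unname(spec$synapses), function(s)
    list(pre = s$pre, post = s$post, g = s$g, U = s$U,
         tau_s = s$tau_s, tau_f = s$tau_f, tau_r = s$tau_r))
  yaml::write_yaml(list(populations = pops, synapses = syns), path,
                   precision = 17L)
  invisible(path)
}

#' @rdname write_circuit
#' @export
read_circuit <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$populations)) stop("config is missing the 'populations' key")
  pops <- lapply(names(cfg$populations), function(lab) {
    p <- cfg$populations[[lab]]
    for (key in c("theta", "beta"))
      if (is.null(p[[key]]))
        stop("population '", lab, "' is missing the '", key, "' key")
    population(lab, theta = p$theta, beta = p$beta,
               tau_a = if (is.null(p$tau_a)) NA_real_ else p$tau_a,
               gbar_a = if (is.null(p$gbar_a)) 0 else p$gbar_a)
  })
  syns <- lapply(cfg$synapses, function(s) {
    for (key in c("pre", "post", "g", "U", "tau_s"))
      if (is.null(s[[key]]))
        stop("a synapse block is missing the '", key, "' key")
    synapse(s$pre, s$post, g = s$g, U = s$U, tau_s = s$tau_s,
            tau_f = if (is.null(s$tau_f)) 0 else s$tau_f,
            tau_r = if (is.null(s$tau_r)) 0 else s$tau_r)
  })
  circuit_spec(pops, syns)
}
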