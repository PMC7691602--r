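# Parameter containers for neurons and synapses.  Plain lists with a class
# tag and eager validation; units are ms, mV, nA, nF, uS throughout.

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_field(field, "must be a single positive finite number")
  x
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_field(field, "must be a single non-negative finite number")
  x
}

check_number <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  x
}

check_m <- function(m) {
  check_number(m, "m")
  if (m >= 2)
    stop_field("m", paste("must be < 2: the explicit spike-time threshold",
                          "theta0 / (1 - m/2) is singular at m = 2"))
  m
}

#' GLIF neuron parameters
#'
#' A generalized leaky integrate-and-fire neuron: a leaky membrane
#' (capacitance `Cmem`, leak conductance `Gmem`, constant offset current
#' `Ibias`) plus a dynamic spike threshold \eqn{\theta} that relaxes toward
#' \eqn{\theta_0 + m U} with time constant `tau_theta`.  When
#' \eqn{U \ge \theta} the membrane is reset to 0; the threshold itself is
#' not reset.
#'
#' @param Cmem membrane capacitance (nF).
#' @param Gmem leak conductance (uS).
#' @param Ibias constant offset current (nA).
#' @param theta0 resting spike threshold (mV above rest); must be positive.
#' @param tau_theta threshold time constant (ms).
#' @param m threshold-voltage proportionality (dimensionless); must be
#'   below 2.  `m < 0` gives a rising frequency transient (the threshold
#'   hyperpolarizes with depolarization), `m > 0` an adapting/falling one.
#' @return An object of class `glif_neuron`.
#' @examples
#' glif_neuron(Cmem = 200, Gmem = 1, Ibias = 0.5, theta0 = 1)
#' @export
glif_neuron <- function(Cmem, Gmem = 1, Ibias = 0, theta0 = 1,
                        tau_theta = 1000, m = 0) {
  structure(list(
    Cmem = check_positive(Cmem, "Cmem"),
    Gmem = check_positive(Gmem, "Gmem"),
    Ibias = check_number(Ibias, "Ibias"),
    theta0 = check_positive(theta0, "theta0"),
    tau_theta = check_positive(tau_theta, "tau_theta"),
    m = check_m(m)), class = "glif_neuron")
}

#' Non-spiking (leaky-integrator) neuron parameters
#'
#' A continuous-voltage leaky integrator whose depolarization stands for
#' the mean activity of a population of spiking neurons.  `R` is the
#' operating range: the depolarization at which the neuron (and any graded
#' synapse it drives) saturates.
#'
#' @param Cmem membrane capacitance (nF).
#' @param Gmem leak conductance (uS).
#' @param Ibias constant offset current (nA).
#' @param R operating-range depolarization (mV).
#' @return An object of class `nonspiking_neuron`.
#' @export
nonspiking_neuron <- function(Cmem, Gmem = 1, Ibias = 0, R = 20) {
  structure(list(
    Cmem = check_positive(Cmem, "Cmem"),
    Gmem = check_positive(Gmem, "Gmem"),
    Ibias = check_number(Ibias, "Ibias"),
    R = check_positive(R, "R")), class = "nonspiking_neuron")
}

#' Spiking synapse parameters
#'
#' A conductance-based synapse whose conductance is reset to `Gmax` each
#' time the pre-synaptic neuron spikes and decays exponentially to 0 with
#' time constant `tau_s`.
#'
#' @param Gmax conductance at reset (uS).
#' @param tau_s decay time constant (ms).
#' @param Es reversal potential (mV above the post-synaptic rest).
#' @return An object of class `spiking_synapse`.
#' @export
spiking_synapse <- function(Gmax, tau_s, Es) {
  structure(list(
    Gmax = check_nonneg(Gmax, "Gmax"),
    tau_s = check_positive(tau_s, "tau_s"),
    Es = check_number(Es, "Es")), class = "spiking_synapse")
}

#' Graded (non-spiking) synapse parameters
#'
#' The conductance is a piecewise-linear function of the pre-synaptic
#' depolarization: 0 below rest, `Gmax_bar` above the operating range `R`,
#' and linear in between.
#'
#' @param Gmax_bar maximum conductance (uS).
#' @param Es reversal potential (mV above the post-synaptic rest).
#' @param R pre-synaptic operating range (mV).
#' @return An object of class `graded_synapse`.
#' @export
graded_synapse <- function(Gmax_bar, Es, R = 20) {
  structure(list(
    Gmax_bar = check_nonneg(Gmax_bar, "Gmax_bar"),
    Es = check_number(Es, "Es"),
    R = check_positive(R, "R")), class = "graded_synapse")
}
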