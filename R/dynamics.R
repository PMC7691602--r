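# Instantaneous dynamics of both neuron models and both synapse models.
# These scalar forms are the reference definitions; the network integrator
# in src/sim.cpp implements the same right-hand sides.

#' Graded synaptic conductance
#'
#' Piecewise-linear activation of a non-spiking synapse:
#' \eqn{G = \bar{G}_{max} \, \mathrm{clip}(U_{pre}/R, 0, 1)}.
#'
#' @param Upre pre-synaptic depolarization (mV); vectorized.
#' @param syn a [graded_synapse()].
#' @return Conductance in uS.
#' @export
graded_conductance <- function(Upre, syn) {
  syn$Gmax_bar * pmin(pmax(Upre / syn$R, 0), 1)
}

#' Membrane derivative of a non-spiking neuron
#'
#' \eqn{d\bar{U}/dt = [-G_{mem}\bar{U} + \sum_i G_{s,i}(E_{s,i}-\bar{U})
#' + I_{app} + I_{bias}] / \bar{C}_{mem}}.
#'
#' @param U membrane depolarization (mV).
#' @param inputs list of `c(conductance, Es)` pairs (uS, mV), or `NULL`.
#' @param Iapp applied current (nA).
#' @param p a [nonspiking_neuron()].
#' @return dU/dt in mV/ms.
#' @export
nonspiking_rhs <- function(U, inputs = NULL, Iapp = 0, p) {
  Isyn <- 0
  for (inp in inputs) {
    if (inp[[1]] < 0) stop("synaptic conductance must be >= 0")
    Isyn <- Isyn + inp[[1]] * (inp[[2]] - U)
  }
  (-p$Gmem * U + Isyn + Iapp + p$Ibias) / p$Cmem
}

#' Steady-state depolarization of a non-spiking neuron
#'
#' The equilibrium of the leaky integrator: a conductance-weighted average
#' of the synaptic reversal potentials plus the current-driven offset,
#' \deqn{\bar{U}_\infty = \frac{\sum_i G_{s,i} E_{s,i} + I_{app} + I_{bias}}
#'                             {\sum_i G_{s,i} + G_{mem}}.}
#' With no synaptic input this reduces to
#' \eqn{(I_{app}+I_{bias})/G_{mem}}.
#'
#' @inheritParams nonspiking_rhs
#' @return Steady-state depolarization in mV.
#' @export
nonspiking_steady_state <- function(inputs = NULL, Iapp = 0, p) {
  num <- Iapp + p$Ibias
  den <- p$Gmem
  for (inp in inputs) {
    num <- num + inp[[1]] * inp[[2]]
    den <- den + inp[[1]]
  }
  if (den <= 0) stop("total conductance must be positive")
  num / den
}

#' Effective membrane time constant
#'
#' \eqn{\tau_{mem} = C_{mem} / (\sum_i G_{s,i} + G_{mem})}: synaptic
#' conductance loads the membrane and shortens the time constant.
#'
#' @param Gs_total summed synaptic conductance (uS).
#' @param p a [nonspiking_neuron()] or [glif_neuron()].
#' @return Time constant in ms.
#' @export
membrane_tau <- function(p, Gs_total = 0) {
  p$Cmem / (p$Gmem + Gs_total)
}

#' Step response of a non-spiking neuron
#'
#' \eqn{\bar{U}(t) = \bar{U}_\infty (1 - e^{-t/\tau_{mem}})}: the response
#' from rest to a tonic input switched on at t = 0.
#'
#' @param t time since stimulus onset (ms); vectorized.
#' @param U_inf steady-state depolarization (mV).
#' @param tau_mem membrane time constant (ms), from [membrane_tau()].
#' @return Depolarization in mV.
#' @export
nonspiking_transient <- function(t, U_inf, tau_mem) {
  if (tau_mem <= 0) stop("tau_mem must be positive")
  U_inf * (1 - exp(-t / tau_mem))
}

#' Membrane and threshold derivatives of a GLIF neuron
#'
#' The membrane obeys the same leaky-integrator equation as the
#' non-spiking model; the threshold relaxes toward
#' \eqn{\theta_0 + m U} with time constant \eqn{\tau_\theta}:
#' \eqn{d\theta/dt = (-\theta + \theta_0 + m U)/\tau_\theta}.
#'
#' @param U membrane depolarization (mV).
#' @param theta current threshold (mV).
#' @param inputs list of `c(conductance, Es)` pairs, or `NULL`.
#' @param Iapp applied current (nA).
#' @param p a [glif_neuron()].
#' @return Named numeric vector `c(dU, dtheta)` in mV/ms.
#' @export
glif_rhs <- function(U, theta, inputs = NULL, Iapp = 0, p) {
  Isyn <- 0
  for (inp in inputs) {
    if (inp[[1]] < 0) stop("synaptic conductance must be >= 0")
    Isyn <- Isyn + inp[[1]] * (inp[[2]] - U)
  }
  c(dU = (-p$Gmem * U + Isyn + Iapp + p$Ibias) / p$Cmem,
    dtheta = (-theta + p$theta0 + p$m * U) / p$tau_theta)
}

#' Spike reset rule
#'
#' Applied when the membrane has reached threshold (`U >= theta`): the
#' membrane is reset to 0 (plus optional Gaussian reset noise) and every
#' outgoing spiking synapse conductance is set to its `Gmax`.  The
#' threshold is not reset.
#'
#' @param U membrane depolarization at the spike (mV).
#' @param theta threshold at the spike (mV).
#' @param outgoing list of [spiking_synapse()] objects driven by this
#'   neuron.
#' @param reset_noise_sd standard deviation of Gaussian reset noise (mV);
#'   0 disables it.
#' @return List with `U` (reset potential) and `Gs` (conductances after
#'   reset, one per outgoing synapse).
#' @export
apply_spike_reset <- function(U, theta, outgoing = list(),
                              reset_noise_sd = 0) {
  if (U < theta)
    stop("reset applied below threshold: U < theta")
  U_new <- if (reset_noise_sd > 0) rnorm(1, 0, reset_noise_sd) else 0
  list(U = U_new, Gs = vapply(outgoing, function(s) s$Gmax, numeric(1)))
}

#' Exponential decay of a spiking synapse conductance
#'
#' Exact update \eqn{G_s(t + \Delta t) = G_s(t) e^{-\Delta t/\tau_s}};
#' being the exact solution of the linear decay equation it is independent
#' of the integrator step size.
#'
#' @param Gs conductance (uS); vectorized.
#' @param dt elapsed time (ms), non-negative.
#' @param tau_s decay constant (ms).
#' @return Conductance in uS.
#' @export
synapse_decay <- function(Gs, dt, tau_s) {
  if (any(dt < 0)) stop("dt must be >= 0")
  Gs * exp(-dt / tau_s)
}
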