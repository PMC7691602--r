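# The functional subnetwork approach (FSA) for spiking pathways: maps
# network-wide activation constants and intended synaptic gains to
# concrete neuron and synapse parameters.

#' Network-wide design context
#'
#' The constants shared by every node of an FSA-designed network: the
#' activation scale (`R`, `Fmax`), the resting spike threshold `theta0`,
#' the synaptic linearity budget `delta`, and the default leak
#' conductance.
#'
#' @param Fmax maximum expected spiking frequency (kHz).
#' @param R operating-range depolarization (mV).
#' @param theta0 resting spike threshold (mV).
#' @param delta target synaptic nonlinearity, in (0, 1): the tolerated
#'   fractional departure of average synaptic conductance from
#'   proportionality to pre-synaptic frequency.
#' @param Gmem leak conductance applied to designed neurons (uS).
#' @return An object of class `design_context`.
#' @export
design_context <- function(Fmax = 0.1, R = 20, theta0 = 1, delta = 0.01,
                           Gmem = 1) {
  if (delta <= 0 || delta >= 1) stop_field("delta", "must lie in (0, 1)")
  structure(list(Fmax = check_positive(Fmax, "Fmax"),
                 R = check_positive(R, "R"),
                 theta0 = check_positive(theta0, "theta0"),
                 delta = delta,
                 Gmem = check_positive(Gmem, "Gmem")),
            class = "design_context")
}

#' Bias current for a designed GLIF neuron
#'
#' \eqn{I_{bias} = G_{mem}\theta_0/(2 - m)}, equal to
#' \eqn{G_{mem}\theta_\infty^*/2} under the explicit threshold
#' approximation.  This centers the affine f-I band so that the neuron is
#' just quiet at zero applied current and its frequency is proportional to
#' the applied current above it.
#'
#' @param Gmem leak conductance (uS).
#' @param theta0 resting threshold (mV).
#' @param m threshold-voltage proportionality, below 2.
#' @return Bias current in nA.
#' @export
design_bias_current <- function(Gmem, theta0, m) {
  check_m(m)
  Gmem * theta0 / (2 - m)
}

#' Membrane time constant for a designed GLIF neuron
#'
#' \eqn{\tau_{mem} = (R/F_{max}) (1 - m/2) / \theta_0}: chosen so the
#' frequency reaches \eqn{F_{max}} when the input current reaches its
#' full-scale value \eqn{G_{mem} R}.
#'
#' @param R operating-range depolarization (mV).
#' @param Fmax maximum expected spiking frequency (kHz).
#' @param theta0 resting threshold (mV).
#' @param m threshold-voltage proportionality, below 2.
#' @return Membrane time constant in ms.
#' @export
design_membrane_tau <- function(R, Fmax, theta0, m) {
  check_m(m)
  (R / Fmax) * (1 - m / 2) / theta0
}

#' Threshold time constant for a desired frequency transient
#'
#' To make the spiking frequency transient decay at the same rate as a
#' non-spiking neuron with membrane time constant `tau_mem_bar`, set
#' \eqn{\tau_\theta = \bar{\tau}_{mem} (1 - m/2)}; the effective
#' spike-time threshold transient then has time constant exactly
#' `tau_mem_bar`.
#'
#' @param tau_mem_bar membrane time constant of the non-spiking analog
#'   (ms).
#' @param m threshold-voltage proportionality, below 2.
#' @return Threshold time constant in ms.
#' @export
design_theta_tau <- function(tau_mem_bar, m) {
  check_m(m)
  check_positive(tau_mem_bar, "tau_mem_bar") * (1 - m / 2)
}

#' Synaptic decay constant from the linearity budget
#'
#' The upper limit \eqn{\tau_s \le -1/(F_{max}\ln\delta)} keeps the
#' average conductance within a fraction `delta` of proportionality to the
#' pre-synaptic frequency over the whole operating range.  The limit
#' itself is returned (and used as the designed value): the longest decay,
#' hence the smoothest post-synaptic drive, within the budget.
#'
#' @param Fmax maximum expected spiking frequency (kHz).
#' @param delta linearity budget in (0, 1).
#' @return Synaptic decay constant in ms.
#' @export
design_synapse_tau <- function(Fmax, delta) {
  if (delta <= 0 || delta >= 1) stop_field("delta", "must lie in (0, 1)")
  -1 / (check_positive(Fmax, "Fmax") * log(delta))
}

#' Maximum conductance from a target average conductance
#'
#' Inverts the conductance-averaging relation at the design point
#' \eqn{f_{sp} = F_{max}}:
#' \eqn{G_{max} = G_{avg} / (\tau_s F_{max} (1 - \delta))}.
#'
#' @param Gavg desired average conductance at full activation (uS).
#' @param tau_s synaptic decay constant (ms).
#' @param Fmax maximum expected spiking frequency (kHz).
#' @param delta linearity budget in (0, 1).
#' @return Maximum (reset) conductance in uS.
#' @export
design_gmax_from_gavg <- function(Gavg, tau_s, Fmax, delta) {
  if (delta < 0 || delta >= 1) stop_field("delta", "must lie in [0, 1)")
  check_nonneg(Gavg, "Gavg") /
    (check_positive(tau_s, "tau_s") * check_positive(Fmax, "Fmax") *
       (1 - delta))
}

#' Maximum conductance from an intended synaptic gain
#'
#' Direct design of a spiking synapse for gain \eqn{k_{syn}} (the ratio of
#' post- to pre-synaptic steady-state activation), assuming
#' \eqn{\delta \approx 0}:
#' \deqn{G_{max} = \frac{k_{syn} R}{(E_s - k_{syn} R)\,\tau_s F_{max}}.}
#'
#' @param k_syn intended gain (dimensionless); negative with a negative
#'   `Es` gives an inhibitory pathway.
#' @param R operating-range depolarization (mV).
#' @param Es synaptic reversal potential (mV above rest).
#' @param tau_s synaptic decay constant (ms).
#' @param Fmax maximum expected spiking frequency (kHz).
#' @return Maximum (reset) conductance in uS.
#' @export
design_gmax_from_gain <- function(k_syn, R, Es, tau_s, Fmax) {
  design_nonspiking_gmax(k_syn, R, Es) /
    (check_positive(tau_s, "tau_s") * check_positive(Fmax, "Fmax"))
}

#' Maximum conductance of a graded synapse from an intended gain
#'
#' The non-spiking gain relation
#' \eqn{\bar{G}_{max} = k_{syn} R / (E_s - k_{syn} R)}.
#'
#' @inheritParams design_gmax_from_gain
#' @return Maximum graded conductance in uS.
#' @export
design_nonspiking_gmax <- function(k_syn, R, Es) {
  check_number(k_syn, "k_syn")
  check_positive(R, "R")
  check_number(Es, "Es")
  if (Es == k_syn * R)
    stop("singular gain: Es equals k_syn * R, no finite conductance ",
         "achieves this gain")
  if (k_syn > 0 && Es < k_syn * R)
    stop("excitatory gain requires Es > k_syn * R")
  k_syn * R / (Es - k_syn * R)
}

#' Design a signal-transmission pathway
#'
#' Runs the full FSA design sequence for a two-node spiking pathway with
#' intended gain `k_syn`:
#' \enumerate{
#'   \item network-wide constants `Fmax`, `R`, `theta0` from `ctx`;
#'   \item transient type via `m` (negative: rising frequency transient;
#'     zero: none; positive: adapting);
#'   \item threshold time constant from the desired transient rate
#'     `tau_mem_bar` (skipped when `m = 0`);
#'   \item bias current;
#'   \item membrane time constant;
#'   \item synaptic decay constant from the linearity budget;
#'   \item maximum synaptic conductance from the gain.
#' }
#' Membrane capacitances follow from the time constant, which is defined
#' with synaptic conductance loading included: the pre-synaptic neuron has
#' \eqn{C_{mem} = \tau_{mem} G_{mem}}, while the post-synaptic neuron has
#' \eqn{C_{mem} = \tau_{mem} (G_{mem} + \bar{G}_{max})} where
#' \eqn{\bar{G}_{max}} is the design-point average conductance of its
#' incoming synapse.  This loading term is what makes the realized gain
#' land on `k_syn`.
#'
#' @param k_syn intended pathway gain.
#' @param Es synaptic reversal potential (mV above rest).
#' @param m threshold-voltage proportionality (below 2); choose the sign
#'   from the desired frequency transient.
#' @param tau_mem_bar for `m != 0`, the membrane time constant of the
#'   non-spiking analog whose transient the pathway should mimic (ms).
#' @param ctx a [design_context()].
#' @return An object of class `fsa_pathway`: a list with the resolved
#'   neuron parameters (`pre`, `post` as [glif_neuron()]), synapse
#'   parameters (`synapse` as [spiking_synapse()]), the graded-equivalent
#'   conductance `Gbar_max`, the design constants, and the predicted
#'   spike-time threshold `theta_star`.
#' @examples
#' # flat-transient pathway with unit gain
#' design_pathway(k_syn = 1, Es = 160, m = 0)
#' # rising-transient variant mimicking a 500 ms non-spiking analog
#' design_pathway(k_syn = 1, Es = 160, m = -5, tau_mem_bar = 500)
#' @export
design_pathway <- function(k_syn = 1, Es = 160, m = 0, tau_mem_bar = NULL,
                           ctx = design_context()) {
  stopifnot(inherits(ctx, "design_context"))
  check_m(m)
  if (m != 0 && is.null(tau_mem_bar))
    stop("tau_mem_bar is required when m != 0: it sets the duration of ",
         "the frequency transient")
  tau_theta <- if (m != 0) design_theta_tau(tau_mem_bar, m)
               else design_membrane_tau(ctx$R, ctx$Fmax, ctx$theta0, 0)
  Ibias <- design_bias_current(ctx$Gmem, ctx$theta0, m)
  tau_mem <- design_membrane_tau(ctx$R, ctx$Fmax, ctx$theta0, m)
  tau_s <- design_synapse_tau(ctx$Fmax, ctx$delta)
  Gmax <- design_gmax_from_gain(k_syn, ctx$R, Es, tau_s, ctx$Fmax)
  Gbar <- design_nonspiking_gmax(k_syn, ctx$R, Es)

  pre <- glif_neuron(Cmem = tau_mem * ctx$Gmem, Gmem = ctx$Gmem,
                     Ibias = Ibias, theta0 = ctx$theta0,
                     tau_theta = tau_theta, m = m)
  post <- glif_neuron(Cmem = tau_mem * (ctx$Gmem + abs(Gbar)),
                      Gmem = ctx$Gmem, Ibias = Ibias,
                      theta0 = ctx$theta0, tau_theta = tau_theta, m = m)

  structure(list(
    ctx = ctx, k_syn = k_syn, Es = Es, m = m,
    tau_mem_bar = tau_mem_bar,
    tau_theta = tau_theta, Ibias = Ibias, tau_mem = tau_mem,
    tau_s = tau_s, Gmax = Gmax, Gbar_max = Gbar,
    theta_star = theta_star_approx(ctx$theta0, m),
    pre = pre, post = post,
    synapse = spiking_synapse(Gmax = Gmax, tau_s = tau_s, Es = Es)),
    class = "fsa_pathway")
}

#' @export
print.fsa_pathway <- function(x, ...) {
  cat("FSA-designed spiking transmission pathway\n")
  cat(sprintf("  activation scale: R = %g mV, Fmax = %g kHz, theta0 = %g mV\n",
              x$ctx$R, x$ctx$Fmax, x$ctx$theta0))
  cat(sprintf("  gain k_syn = %g, Es = %g mV, m = %g\n",
              x$k_syn, x$Es, x$m))
  cat(sprintf("  neuron:  Ibias = %.4g nA, tau_mem = %.4g ms%s\n",
              x$Ibias, x$tau_mem,
              if (x$m != 0) sprintf(", tau_theta = %.4g ms", x$tau_theta)
              else ""))
  cat(sprintf("  synapse: tau_s = %.4g ms, Gmax = %.4g uS (delta = %g)\n",
              x$tau_s, x$Gmax, x$ctx$delta))
  invisible(x)
}

#' @export
summary.fsa_pathway <- function(object, Iapp = c(5, 10, 20), ...) {
  pred <- predict(object, Iapp = Iapp)
  print(object)
  cat("\nAnalytic predictions:\n")
  print(pred, row.names = FALSE, digits = 4)
  invisible(pred)
}

#' @export
coef.fsa_pathway <- function(object, ...) {
  c(Ibias = object$Ibias, tau_mem = object$tau_mem,
    tau_theta = object$tau_theta, tau_s = object$tau_s,
    Gmax = object$Gmax, Gbar_max = object$Gbar_max,
    Cmem_pre = object$pre$Cmem, Cmem_post = object$post$Cmem)
}

#' Analytic frequency predictions for a designed pathway
#'
#' For each applied current, computes the pre-synaptic target voltage and
#' steady frequency, the average synaptic conductance it produces, and the
#' post-synaptic steady frequency under that (constant) conductance load,
#' all from the closed-form machinery.  `f_intended` is the design target
#' \eqn{k_{syn} F_{max} I_{app} / (G_{mem} R)}.
#'
#' @param object an `fsa_pathway`.
#' @param Iapp applied currents to the pre-synaptic neuron (nA).
#' @param ... unused.
#' @return Data frame with columns `Iapp`, `f_intended`, `f_pre`, `Gavg`,
#'   `f_post`, `theta_star_pre`, `theta_star_post` (kHz, uS, mV).
#' @export
predict.fsa_pathway <- function(object, Iapp = c(5, 10, 20), ...) {
  d <- object
  rows <- lapply(Iapp, function(I) {
    U_pre <- (I + d$Ibias) / d$ctx$Gmem
    tau_pre <- membrane_tau(d$pre)
    ts_pre <- if (U_pre > 0) solve_theta_star(U_pre, d$pre, tau_pre)
              else d$ctx$theta0
    f_pre <- spiking_frequency(U_pre, ts_pre, tau_pre)
    Gavg <- average_conductance(d$Gmax, d$tau_s, f_pre)
    U_post <- nonspiking_steady_state(
      list(c(Gavg, d$Es)), Iapp = 0,
      p = nonspiking_neuron(Cmem = d$post$Cmem, Gmem = d$ctx$Gmem,
                            Ibias = d$Ibias, R = d$ctx$R))
    tau_post <- membrane_tau(d$post, Gs_total = Gavg)
    ts_post <- if (U_post > 0) solve_theta_star(U_post, d$post, tau_post)
               else d$ctx$theta0
    f_post <- spiking_frequency(U_post, ts_post, tau_post)
    data.frame(Iapp = I,
               f_intended = d$k_syn * d$ctx$Fmax * I /
                 (d$ctx$Gmem * d$ctx$R),
               f_pre = f_pre, Gavg = Gavg, f_post = f_post,
               theta_star_pre = ts_pre, theta_star_post = ts_post)
  })
  do.call(rbind, rows)
}
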