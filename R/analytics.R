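# Closed-form and root-finding characterizations of GLIF behavior:
# steady-state and transient spiking frequency, the implicit spike-time
# threshold, frequency bounds, and time-averaged synaptic conductance.

#' Steady-state threshold
#'
#' The equilibrium of the threshold dynamics at a held membrane voltage:
#' \eqn{\theta_\infty = \theta_0 + m U_\infty}.
#'
#' @param theta0 resting threshold (mV).
#' @param m threshold-voltage proportionality.
#' @param U_inf target voltage (mV): the steady-state depolarization the
#'   membrane would reach with spiking disabled.
#' @return Threshold in mV.
#' @export
steady_state_threshold <- function(theta0, m, U_inf) {
  theta0 + m * U_inf
}

#' Steady-state spiking frequency
#'
#' The inverse of the time the membrane takes to charge from the reset
#' potential to the threshold along its exponential approach to the target
#' voltage:
#' \deqn{f_{sp} = \frac{-1}{\tau_{mem} \ln(1 - \theta/U_\infty)}.}
#' When the target voltage does not exceed the threshold no spiking can
#' occur; the frequency is returned as 0 so that f-I curves are total
#' functions.
#'
#' @param U_inf target voltage (mV); vectorized.
#' @param theta spike threshold (mV); for a dynamic threshold pass the
#'   spike-time threshold from [solve_theta_star()].
#' @param tau_mem membrane time constant (ms), including any synaptic
#'   conductance loading ([membrane_tau()]).
#' @return Frequency in kHz.
#' @export
spiking_frequency <- function(U_inf, theta, tau_mem) {
  if (tau_mem <= 0) stop("tau_mem must be positive")
  if (any(theta <= 0 & U_inf > 0))
    stop("invalid threshold: theta must be positive when U_inf > 0")
  f <- ifelse(U_inf > theta, -1 / (tau_mem * log(1 - theta / U_inf)), 0)
  unname(f)
}

theta_star_implicit <- function(theta_star, U_inf, theta_inf, m,
                                tau_mem, tau_theta) {
  x <- 1 - theta_star / U_inf
  if (abs(tau_mem - tau_theta) < 1e-6 * tau_theta) {
    (theta_inf - theta_star) * theta_star / U_inf +
      m * U_inf * x * log(x)
  } else {
    p <- tau_mem / tau_theta
    (theta_inf - theta_star) * (1 - x^p) +
      m * U_inf * tau_mem / (tau_theta - tau_mem) * (x - x^p)
  }
}

#' Spike-time threshold during steady spiking
#'
#' With a dynamic threshold (\eqn{m \neq 0}) the threshold value at the
#' instant of each spike, \eqn{\theta_\infty^*}, settles to the root of an
#' implicit equation coupling the membrane and threshold trajectories over
#' one interspike interval.  The root is bracketed in
#' \eqn{(0, U_\infty)} and found with Brent's method; the equation has two
#' printed branches, for \eqn{\tau_{mem} = \tau_\theta} and otherwise, and
#' the equal-\eqn{\tau} branch is selected when the two time constants
#' agree to within one part in 1e6 (the general branch suffers
#' catastrophic cancellation near equality).  For `m = 0` the threshold is constant and `theta0` is
#' returned exactly.
#'
#' @param U_inf target voltage (mV), must be positive.
#' @param p a [glif_neuron()].
#' @param tau_mem membrane time constant (ms); defaults to
#'   `p$Cmem / p$Gmem`.
#' @param tol relative root tolerance.
#' @return Spike-time threshold in mV.
#' @seealso [theta_star_approx()] for the explicit high-frequency
#'   approximation.
#' @export
solve_theta_star <- function(U_inf, p, tau_mem = p$Cmem / p$Gmem,
                             tol = 1e-12) {
  if (U_inf <= 0) stop("U_inf must be positive")
  if (p$m == 0) return(p$theta0)
  theta_inf <- steady_state_threshold(p$theta0, p$m, U_inf)
  eps <- 1e-9
  lo <- eps * U_inf
  hi <- (1 - eps) * U_inf
  flo <- theta_star_implicit(lo, U_inf, theta_inf, p$m, tau_mem,
                             p$tau_theta)
  fhi <- theta_star_implicit(hi, U_inf, theta_inf, p$m, tau_mem,
                             p$tau_theta)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop("no spike-time threshold in (0, U_inf): ",
         "the neuron cannot spike steadily at this target voltage")
  uniroot(theta_star_implicit, c(lo, hi), U_inf = U_inf,
          theta_inf = theta_inf, m = p$m, tau_mem = tau_mem,
          tau_theta = p$tau_theta, tol = tol * U_inf)$root
}

#' Explicit approximation of the spike-time threshold
#'
#' At high spiking frequency the membrane voltage averages to about half
#' the spike-time threshold, which gives the explicit fixed point
#' \deqn{\theta_\infty^* = \frac{\theta_0}{1 - m/2} = B \theta_0.}
#' Accurate when the interspike interval is much shorter than
#' \eqn{\tau_\theta}; singular at \eqn{m = 2}.
#'
#' @param theta0 resting threshold (mV).
#' @param m threshold-voltage proportionality, below 2.
#' @return Approximate spike-time threshold in mV.
#' @export
theta_star_approx <- function(theta0, m) {
  check_m(m)
  theta0 / (1 - m / 2)
}

#' Affine bounds on the f-I curve
#'
#' Although the exact steady-state frequency is a transcendental function
#' of the applied current, it is pinched between two parallel lines
#' separated by \eqn{1/\tau_{mem}}:
#' \deqn{\frac{I_{app}}{G_{mem}\tau_{mem}\theta_\infty^*} \pm
#'       \frac{1}{2\tau_{mem}}.}
#' The bounds assume the bias current is tuned to
#' \eqn{G_{mem}\theta_\infty^*/2} (see [design_bias_current()]).
#'
#' @param Iapp applied current (nA); vectorized.
#' @param Gmem leak conductance (uS).
#' @param tau_mem membrane time constant (ms).
#' @param theta_star spike-time threshold (mV).
#' @return Data frame with columns `lower` and `upper` (kHz).
#' @export
frequency_bounds <- function(Iapp, Gmem, tau_mem, theta_star) {
  mid <- linear_frequency_approx(Iapp, Gmem, tau_mem, theta_star)
  data.frame(lower = mid - 1 / (2 * tau_mem),
             upper = mid + 1 / (2 * tau_mem))
}

#' Linear f-I approximation
#'
#' The midline of the affine frequency bounds:
#' \eqn{f_{sp} \approx I_{app} / (G_{mem}\tau_{mem}\theta_\infty^*)}.
#'
#' @inheritParams frequency_bounds
#' @return Frequency in kHz.
#' @export
linear_frequency_approx <- function(Iapp, Gmem, tau_mem, theta_star) {
  if (tau_mem <= 0 || theta_star <= 0)
    stop("tau_mem and theta_star must be positive")
  Iapp / (Gmem * tau_mem * theta_star)
}

#' Activation scale
#'
#' The shared currency between the models: a non-spiking neuron's
#' depolarization on \eqn{[0, R]} and a spiking neuron's frequency on
#' \eqn{[0, F_{max}]} represent the same normalized activation,
#' \eqn{\bar{U}/R = f_{sp}/F_{max}}.
#'
#' @param R operating-range depolarization (mV).
#' @param Fmax maximum expected spiking frequency (kHz).
#' @return An object of class `activation_scale`.
#' @export
activation_scale <- function(R = 20, Fmax = 0.1) {
  structure(list(R = check_positive(R, "R"),
                 Fmax = check_positive(Fmax, "Fmax")),
            class = "activation_scale")
}

#' Map depolarization to equivalent spiking frequency
#'
#' \eqn{f = (F_{max}/R)\,\bar{U}}.
#'
#' @param U_bar depolarization (mV); vectorized.
#' @param scale an [activation_scale()].
#' @return Frequency in kHz.
#' @export
activation_to_frequency <- function(U_bar, scale) {
  scale$Fmax / scale$R * U_bar
}

#' Map spiking frequency to equivalent depolarization
#'
#' Inverse of [activation_to_frequency()]: \eqn{\bar{U} = (R/F_{max}) f}.
#'
#' @param f frequency (kHz); vectorized.
#' @param scale an [activation_scale()].
#' @return Depolarization in mV.
#' @export
frequency_to_activation <- function(f, scale) {
  scale$R / scale$Fmax * f
}

#' Spike-to-spike threshold transient
#'
#' After a step input the spike-time threshold relaxes from \eqn{\theta_0}
#' to \eqn{\theta_\infty^*} with effective time constant
#' \eqn{\tau_\theta^* = B \tau_\theta}, \eqn{B = 1/(1 - m/2)}:
#' \deqn{\theta^*(t) = \theta_\infty^* +
#'       (\theta_0 - \theta_\infty^*) e^{-t/\tau_\theta^*}.}
#' This is what makes a spiking neuron's smoothed frequency transient
#' mirror a non-spiking neuron's voltage transient.
#'
#' @param t time since stimulus onset (ms); vectorized.
#' @param theta0 resting threshold (mV).
#' @param theta_star_inf asymptotic spike-time threshold (mV).
#' @param tau_theta threshold time constant (ms).
#' @param m threshold-voltage proportionality, below 2.
#' @return Threshold in mV.
#' @export
threshold_transient <- function(t, theta0, theta_star_inf, tau_theta, m) {
  check_m(m)
  tau_star <- tau_theta / (1 - m / 2)
  theta_star_inf + (theta0 - theta_star_inf) * exp(-t / tau_star)
}

#' Time-averaged spiking synapse conductance
#'
#' Averaging the exponential conductance decay over one steady interspike
#' period gives
#' \deqn{G_{avg} = G_{max} \tau_s f_{sp} (1 - e^{-1/(f_{sp}\tau_s)}),}
#' which is proportional to the pre-synaptic frequency up to the
#' nonlinearity term \eqn{\delta} (see [delta_nonlinearity()]).  Returns 0
#' at zero frequency and saturates at `Gmax` as the frequency grows.
#'
#' @param Gmax conductance at reset (uS).
#' @param tau_s decay constant (ms).
#' @param f_sp pre-synaptic spiking frequency (kHz); vectorized,
#'   non-negative.
#' @return Average conductance in uS.
#' @export
average_conductance <- function(Gmax, tau_s, f_sp) {
  if (tau_s <= 0) stop("tau_s must be positive")
  if (any(f_sp < 0)) stop("f_sp must be >= 0")
  ifelse(f_sp > 0, Gmax * tau_s * f_sp * (1 - exp(-1 / (f_sp * tau_s))), 0)
}

#' Synaptic nonlinearity
#'
#' \eqn{\delta = e^{-1/(f_{sp}\tau_s)}}: the fractional departure of the
#' average conductance from proportionality to the pre-synaptic frequency.
#' Small \eqn{\delta} (short \eqn{\tau_s}) makes the synapse an
#' approximately linear frequency-to-conductance converter.
#'
#' @param f_sp spiking frequency (kHz), positive; vectorized.
#' @param tau_s decay constant (ms).
#' @return Dimensionless value in (0, 1).
#' @export
delta_nonlinearity <- function(f_sp, tau_s) {
  if (tau_s <= 0) stop("tau_s must be positive")
  if (any(f_sp <= 0)) stop("f_sp must be positive")
  exp(-1 / (f_sp * tau_s))
}

#' f-I curve of a GLIF neuron
#'
#' Tabulates, for each applied current, the exact steady-state frequency,
#' the linear approximation, the affine bounds and the spike-time
#' threshold.
#'
#' @param p a [glif_neuron()].
#' @param Iapp applied currents (nA).
#' @param file optional path; if given the table is also written as CSV.
#' @return Data frame with columns `Iapp`, `f_exact`, `f_approx`,
#'   `f_lower`, `f_upper`, `theta_star`.
#' @export
fi_curve <- function(p, Iapp, file = NULL) {
  tau_mem <- membrane_tau(p)
  rows <- lapply(Iapp, function(I) {
    U_inf <- (I + p$Ibias) / p$Gmem
    ts <- if (U_inf > 0)
      tryCatch(solve_theta_star(U_inf, p, tau_mem),
               error = function(e) NA_real_)
    else NA_real_
    if (is.na(ts)) {
      # neuron cannot spike steadily here; the curve stays total with f = 0
      return(data.frame(Iapp = I, f_exact = 0, f_approx = NA_real_,
                        f_lower = NA_real_, f_upper = NA_real_,
                        theta_star = NA_real_))
    }
    b <- frequency_bounds(I, p$Gmem, tau_mem, ts)
    data.frame(Iapp = I,
               f_exact = spiking_frequency(U_inf, ts, tau_mem),
               f_approx = linear_frequency_approx(I, p$Gmem, tau_mem, ts),
               f_lower = b$lower, f_upper = b$upper, theta_star = ts)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
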