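# Spike-train and trajectory statistics: instantaneous and mean
# frequencies, population summaries, and errors against analytic
# predictions.

#' Instantaneous spiking frequency
#'
#' The inverse of each interspike interval, timestamped at the later
#' spike of the pair.
#'
#' @param spike_times strictly increasing spike times (ms).
#' @return Data frame with columns `time` (ms) and `f` (kHz); empty with
#'   fewer than two spikes.
#' @export
instantaneous_frequency <- function(spike_times) {
  if (length(spike_times) >= 2 && any(diff(spike_times) <= 0))
    stop("spike times must be strictly increasing")
  if (length(spike_times) < 2)
    return(data.frame(time = numeric(), f = numeric()))
  data.frame(time = spike_times[-1], f = 1 / diff(spike_times))
}

#' Boxcar-smoothed frequency trace
#'
#' Centered moving average of an instantaneous-frequency trace, for
#' Fig-style smoothed transients.
#'
#' @param trace data frame from [instantaneous_frequency()].
#' @param width window width in samples (odd numbers keep centering
#'   exact).
#' @return Data frame with the same columns.
#' @export
smooth_frequency_trace <- function(trace, width = 5) {
  if (nrow(trace) < width) return(trace)
  k <- rep(1 / width, width)
  f <- stats::filter(trace$f, k, sides = 2)
  keep <- !is.na(f)
  data.frame(time = trace$time[keep], f = as.numeric(f[keep]))
}

#' Steady-state frequency from a spike train
#'
#' Mean instantaneous frequency over the final fraction of the simulated
#' duration.
#'
#' @param spike_times strictly increasing spike times (ms).
#' @param duration total simulated duration (ms).
#' @param tail_fraction fraction of the duration treated as steady state.
#' @return Frequency in kHz.
#' @export
steady_state_frequency <- function(spike_times, duration,
                                   tail_fraction = 0.25) {
  tr <- instantaneous_frequency(spike_times)
  tr <- tr[tr$time >= (1 - tail_fraction) * duration, , drop = FALSE]
  if (nrow(tr) == 0)
    stop("no interspike intervals in the steady-state window")
  mean(tr$f)
}

#' Population mean frequency on a time grid
#'
#' Zero-order-hold average: at each grid point, each neuron contributes
#' its most recent instantaneous frequency (0 before its second spike),
#' and the population value is the mean across neurons.
#'
#' @param spike_lists list of spike-time vectors, one per neuron.
#' @param grid evaluation times (ms).
#' @return Data frame with columns `time` and `f` (kHz).
#' @export
population_frequency <- function(spike_lists, grid) {
  if (length(spike_lists) == 0) stop("need at least one neuron")
  per <- vapply(spike_lists, function(st) {
    tr <- instantaneous_frequency(st)
    if (nrow(tr) == 0) return(rep(0, length(grid)))
    idx <- findInterval(grid, tr$time)
    ifelse(idx > 0, tr$f[pmax(idx, 1)], 0)
  }, numeric(length(grid)))
  per <- matrix(per, nrow = length(grid))
  data.frame(time = grid, f = rowMeans(per))
}

#' Relative prediction error
#'
#' \eqn{(f_{measured} - f_{predicted}) / f_{predicted}}.
#'
#' @param measured measured frequency (kHz); vectorized.
#' @param predicted predicted frequency (kHz), positive.
#' @return Signed relative error.
#' @export
prediction_error <- function(measured, predicted) {
  if (any(predicted <= 0)) stop("predicted frequency must be positive")
  (measured - predicted) / predicted
}

#' Residuals between a spiking transient and its non-spiking analog
#'
#' At each spike time, the instantaneous frequency minus the equivalent
#' frequency of the non-spiking voltage trace,
#' \eqn{(F_{max}/R)\bar{U}(t)} — the activation-normalized comparison of
#' the two models' transients.
#'
#' @param spike_times strictly increasing spike times (ms).
#' @param t,U_bar the non-spiking voltage trajectory (ms, mV); linearly
#'   interpolated at spike times.
#' @param scale an [activation_scale()].
#' @return Data frame with columns `time`, `f_inst`, `f_equiv`,
#'   `residual` (kHz).
#' @export
transient_frequency_comparison <- function(spike_times, t, U_bar,
                                           scale) {
  tr <- instantaneous_frequency(spike_times)
  if (nrow(tr) == 0)
    return(data.frame(time = numeric(), f_inst = numeric(),
                      f_equiv = numeric(), residual = numeric()))
  U_at <- approx(t, U_bar, xout = tr$time, rule = 2)$y
  f_eq <- activation_to_frequency(U_at, scale)
  data.frame(time = tr$time, f_inst = tr$f, f_equiv = f_eq,
             residual = tr$f - f_eq)
}

#' Exponential decay constant by log-linear fit
#'
#' Fits \eqn{|y| = A e^{-t/\tau}} by least squares on
#' \eqn{\log|y|}; used to measure the decay rate of frequency-transient
#' residuals.
#'
#' @param t times (ms).
#' @param y values whose magnitude decays exponentially.
#' @param min_mag values with |y| below this are dropped (log safety).
#' @return Fitted time constant \eqn{\tau} in ms.
#' @export
fit_decay_tau <- function(t, y, min_mag = 1e-12) {
  keep <- abs(y) > min_mag
  if (sum(keep) < 3) stop("too few points for a decay fit")
  fit <- lm(log(abs(y[keep])) ~ t[keep])
  slope <- coef(fit)[[2]]
  if (slope >= 0) stop("values do not decay")
  -1 / slope
}
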