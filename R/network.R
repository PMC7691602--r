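# Network assembly and forward-Euler simulation.

#' Assemble a network specification
#'
#' A network is a pair of data frames.  `neurons` has one row per neuron
#' with columns `type` ("glif" or "nonspiking"), `Cmem`, `Gmem`, `Ibias`,
#' `theta0`, `tau_theta`, `m` (the last three ignored for non-spiking
#' neurons and may be `NA`).  `synapses` has one row per synapse with
#' columns `pre`, `post` (1-based neuron indices), `type` ("spiking" or
#' "graded"), `Gmax`, `tau_s`, `Es`, `R` (`tau_s` for spiking, `R` for
#' graded; the other may be `NA`).  All invariants are checked eagerly
#' with errors naming the offending field.
#'
#' @param neurons neuron data frame (see Details).
#' @param synapses synapse data frame; may be empty or `NULL`.
#' @return An object of class `glif_network`.
#' @export
glif_network <- function(neurons, synapses = NULL) {
  neurons <- as.data.frame(neurons)
  need <- c("type", "Cmem", "Gmem", "Ibias", "theta0", "tau_theta", "m")
  for (col in c("Ibias", "theta0", "tau_theta", "m"))
    if (is.null(neurons[[col]])) neurons[[col]] <- NA_real_
  missing <- setdiff(c("type", "Cmem", "Gmem"), names(neurons))
  if (length(missing))
    stop("neurons is missing column(s): ", paste(missing, collapse = ", "))
  neurons <- neurons[need]
  if (!all(neurons$type %in% c("glif", "nonspiking")))
    stop_field("type", "must be 'glif' or 'nonspiking'")
  neurons$Ibias[is.na(neurons$Ibias)] <- 0
  spk <- neurons$type == "glif"
  neurons$theta0[!spk] <- NA_real_
  neurons$tau_theta[!spk] <- NA_real_
  neurons$m[!spk] <- NA_real_
  if (any(!is.finite(neurons$Cmem)) || any(neurons$Cmem <= 0))
    stop_field("Cmem", "must be positive for every neuron")
  if (any(!is.finite(neurons$Gmem)) || any(neurons$Gmem <= 0))
    stop_field("Gmem", "must be positive for every neuron")
  if (any(spk)) {
    if (any(!is.finite(neurons$theta0[spk])) ||
        any(neurons$theta0[spk] <= 0))
      stop_field("theta0", "must be positive for every glif neuron")
    if (any(!is.finite(neurons$tau_theta[spk])) ||
        any(neurons$tau_theta[spk] <= 0))
      stop_field("tau_theta", "must be positive for every glif neuron")
    if (any(!is.finite(neurons$m[spk])) || any(neurons$m[spk] >= 2))
      stop_field("m", "must be finite and < 2 for every glif neuron")
  }

  if (is.null(synapses) || nrow(as.data.frame(synapses)) == 0L) {
    synapses <- data.frame(pre = integer(), post = integer(),
                           type = character(), Gmax = numeric(),
                           tau_s = numeric(), Es = numeric(),
                           R = numeric())
  } else {
    synapses <- as.data.frame(synapses)
    for (col in c("tau_s", "R"))
      if (is.null(synapses[[col]])) synapses[[col]] <- NA_real_
    missing <- setdiff(c("pre", "post", "type", "Gmax", "Es"),
                       names(synapses))
    if (length(missing))
      stop("synapses is missing column(s): ",
           paste(missing, collapse = ", "))
    synapses <- synapses[c("pre", "post", "type", "Gmax", "tau_s", "Es",
                           "R")]
    n <- nrow(neurons)
    if (!all(synapses$pre %in% seq_len(n)))
      stop_field("pre", "must index a neuron row")
    if (!all(synapses$post %in% seq_len(n)))
      stop_field("post", "must index a neuron row")
    if (!all(synapses$type %in% c("spiking", "graded")))
      stop_field("type", "must be 'spiking' or 'graded'")
    if (any(!is.finite(synapses$Gmax)) || any(synapses$Gmax < 0))
      stop_field("Gmax", "must be >= 0 for every synapse")
    sp <- synapses$type == "spiking"
    if (any(sp) && (any(!is.finite(synapses$tau_s[sp])) ||
                    any(synapses$tau_s[sp] <= 0)))
      stop_field("tau_s", "must be positive for every spiking synapse")
    if (any(sp) && any(neurons$type[synapses$pre[sp]] != "glif"))
      stop_field("pre", "spiking synapses need a glif pre-synaptic neuron")
    if (any(!sp) && (any(!is.finite(synapses$R[!sp])) ||
                     any(synapses$R[!sp] <= 0)))
      stop_field("R", "must be positive for every graded synapse")
    synapses$tau_s[!sp] <- NA_real_
    synapses$R[sp] <- NA_real_
  }
  structure(list(neurons = neurons, synapses = synapses),
            class = "glif_network")
}

#' @export
print.glif_network <- function(x, ...) {
  cat(sprintf("glif_network: %d neuron(s) (%d spiking), %d synapse(s)\n",
              nrow(x$neurons), sum(x$neurons$type == "glif"),
              nrow(x$synapses)))
  invisible(x)
}

#' Step stimulus specification
#'
#' Piecewise-constant applied current: one row per (neuron, interval,
#' amplitude).  Overlapping rows on the same neuron add.
#'
#' @param neuron 1-based neuron index (recycled).
#' @param amp amplitude (nA).
#' @param t_start,t_end interval (ms); `t_end = Inf` holds to the end.
#' @return Data frame with columns `neuron`, `t_start`, `t_end`, `amp`.
#' @export
stim_step <- function(neuron, amp, t_start = 0, t_end = Inf) {
  data.frame(neuron = neuron, t_start = t_start, t_end = t_end,
             amp = amp)
}

#' Automatic integration time step
#'
#' The rule \eqn{\Delta t = \min_i(\tau_{mem,i}) \times 10^{-4}} ms, with
#' \eqn{\tau_{mem} = C_{mem}/G_{mem}}: four orders of magnitude below the
#' fastest membrane, so that spike-time discretization error is negligible
#' against the analytic predictions.
#'
#' @param net a [glif_network()].
#' @return Time step in ms.
#' @export
auto_timestep <- function(net) {
  stopifnot(inherits(net, "glif_network"))
  if (nrow(net$neurons) == 0L) stop("network has no neurons")
  min(net$neurons$Cmem / net$neurons$Gmem) * 1e-4
}

#' Random initial state
#'
#' Spiking neurons start at a uniformly random depolarization in
#' \eqn{[0, \theta_0]} (which desynchronizes identical neurons),
#' thresholds at \eqn{\theta_0}, non-spiking neurons at rest, and all
#' synaptic conductances at 0.
#'
#' @param net a [glif_network()].
#' @param seed optional integer seed for reproducibility.
#' @return List with `U`, `theta` (per neuron) and `Gs` (per synapse).
#' @export
initialize_state <- function(net, seed = NULL) {
  stopifnot(inherits(net, "glif_network"))
  if (!is.null(seed)) set.seed(seed)
  spk <- net$neurons$type == "glif"
  U <- numeric(nrow(net$neurons))
  U[spk] <- runif(sum(spk), 0, net$neurons$theta0[spk])
  theta <- ifelse(spk, net$neurons$theta0, 0)
  list(U = U, theta = as.numeric(theta),
       Gs = numeric(nrow(net$synapses)))
}

#' Simulate a network with forward Euler
#'
#' Integrates the coupled membrane, threshold and synapse dynamics with
#' the forward Euler method.  Within each step: states are updated from
#' their values at the start of the step; spiking conductances decay by
#' the exact exponential factor; threshold crossings (`U >= theta`) are
#' detected at the end of the step; crossed neurons are reset to 0 (plus
#' optional Gaussian reset noise) and their outgoing spiking conductances
#' jump to `Gmax`.
#'
#' @param net a [glif_network()].
#' @param stim stimulus data frame from [stim_step()] (rows may be
#'   concatenated with `rbind`), or `NULL` for no applied current.
#' @param duration simulated time (ms).
#' @param dt time step (ms); defaults to [auto_timestep()].
#' @param seed optional integer seed controlling the random initial state
#'   and reset noise.
#' @param init initial state as from [initialize_state()]; defaults to a
#'   fresh random draw.
#' @param reset_noise_sd standard deviation of Gaussian reset noise (mV);
#'   default 0 (deterministic resets).
#' @param record_every record every this-many steps; default aims at
#'   roughly 2000 samples.
#' @param record_gs also record synaptic conductance trajectories.
#' @param t_start simulation start time (ms); spike times and samples are
#'   reported on this clock.
#' @param guard instability guard (mV): the integrator stops with an
#'   error if any |U| exceeds it.
#' @return An object of class `glif_sim`: list with `time`, matrices `U`
#'   and `theta` (samples x neurons), optional `Gs`, `spikes` (list of
#'   spike-time vectors per neuron), `spike_theta` (threshold value at
#'   each spike), `state` (final state, reusable as `init`), `dt`, and
#'   `net`.
#' @export
simulate_network <- function(net, stim = NULL, duration = 1000,
                             dt = NULL, seed = NULL, init = NULL,
                             reset_noise_sd = 0, record_every = NULL,
                             record_gs = FALSE, t_start = 0,
                             guard = 1e4) {
  stopifnot(inherits(net, "glif_network"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dt)) dt <- auto_timestep(net)
  if (dt <= 0 || duration <= dt)
    stop("need dt > 0 and duration > dt")
  if (is.null(init)) init <- initialize_state(net)
  if (is.null(record_every))
    record_every <- max(1L, as.integer(floor(duration / dt / 2000)))
  nrn <- net$neurons
  syn <- net$synapses
  if (is.null(stim) || nrow(stim) == 0L) {
    stim_m <- matrix(numeric(0), ncol = 4)
  } else {
    if (!all(stim$neuron %in% seq_len(nrow(nrn))))
      stop_field("neuron", "stimulus must target an existing neuron")
    stim_m <- cbind(stim$neuron - 1, stim$t_start, stim$t_end, stim$amp)
  }
  spk <- as.integer(nrn$type == "glif")
  res <- sim_core_cpp(
    spk, nrn$Cmem, nrn$Gmem, nrn$Ibias,
    ifelse(spk == 1L, nrn$theta0, 1), ifelse(spk == 1L, nrn$tau_theta, 1),
    ifelse(spk == 1L, nrn$m, 0),
    as.integer(syn$pre - 1L), as.integer(syn$post - 1L),
    as.integer(syn$type == "spiking"),
    syn$Gmax, ifelse(is.na(syn$tau_s), 1, syn$tau_s), syn$Es,
    ifelse(is.na(syn$R), 1, syn$R),
    stim_m, dt, duration, t_start,
    init$U, init$theta, init$Gs,
    reset_noise_sd, as.integer(record_every), record_gs, guard)
  res$dt <- dt
  res$net <- net
  class(res) <- "glif_sim"
  res
}

#' @export
print.glif_sim <- function(x, ...) {
  nsp <- vapply(x$spikes, length, integer(1))
  cat(sprintf(
    "glif_sim: %d neuron(s), t = [%g, %g] ms, dt = %g ms, %d spike(s)\n",
    ncol(x$U), x$time[1], x$time[length(x$time)], x$dt, sum(nsp)))
  invisible(x)
}

#' @export
plot.glif_sim <- function(x, neurons = NULL, what = c("U", "theta"),
                          ...) {
  what <- match.arg(what)
  if (is.null(neurons)) neurons <- seq_len(min(4L, ncol(x$U)))
  y <- x[[what]][, neurons, drop = FALSE]
  graphics::matplot(x$time, y, type = "l", lty = 1,
                    xlab = "time (ms)",
                    ylab = if (what == "U") "U (mV)" else "theta (mV)",
                    ...)
  invisible(x)
}

#' Build a population transmission pathway
#'
#' Expands a designed two-node pathway into two all-to-all connected
#' populations of `N` neurons each (`N^2` synapses).  The designed
#' single-synapse `Gmax` is distributed across each post-synaptic
#' neuron's `N` incoming synapses:
#' \describe{
#'   \item{`"normalized"`}{uniform random weights rescaled so each post
#'     neuron's incoming conductances sum exactly to the designed `Gmax`
#'     (total drive preserved per neuron; the analytic predictions apply
#'     to every neuron).}
#'   \item{`"raw_uniform"`}{independent draws from
#'     \eqn{U(0, 2 G_{max}/N)}: per-neuron totals vary around `Gmax` and
#'     concentrate as `N` grows, so population averaging visibly improves
#'     encoding accuracy.}
#' }
#' All pre-synaptic neurons share any stimulus targeted at the pathway
#' input (see [simulate.fsa_pathway()]).
#'
#' @param design an `fsa_pathway` from [design_pathway()].
#' @param N neurons per population.
#' @param seed optional integer seed for the conductance split.
#' @param split conductance-split rule; see Details.
#' @return A [glif_network()] whose first `N` neurons are the
#'   pre-synaptic population and last `N` the post-synaptic population.
#' @export
build_population_pathway <- function(design, N = 1, seed = NULL,
                                     split = c("normalized",
                                               "raw_uniform")) {
  stopifnot(inherits(design, "fsa_pathway"))
  split <- match.arg(split)
  if (N < 1) stop_field("N", "must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  nrn <- function(p) data.frame(
    type = "glif", Cmem = p$Cmem, Gmem = p$Gmem, Ibias = p$Ibias,
    theta0 = p$theta0, tau_theta = p$tau_theta, m = p$m)
  neurons <- do.call(rbind, c(replicate(N, nrn(design$pre),
                                        simplify = FALSE),
                              replicate(N, nrn(design$post),
                                        simplify = FALSE)))
  w <- matrix(runif(N * N), nrow = N)     # rows: post, cols: pre
  G <- switch(split,
    normalized = design$Gmax * w / rowSums(w),
    raw_uniform = 2 * design$Gmax / N * w)
  synapses <- data.frame(
    pre = rep(seq_len(N), each = N),
    post = rep(N + seq_len(N), times = N),
    type = "spiking",
    Gmax = as.vector(G),                  # column-major: post varies first
    tau_s = design$tau_s, Es = design$Es, R = NA_real_)
  glif_network(neurons, synapses)
}

#' Simulate a designed pathway
#'
#' Convenience front end: builds the (population) network for an
#' `fsa_pathway`, applies a step current to every pre-synaptic neuron and
#' integrates.
#'
#' @param object an `fsa_pathway`.
#' @param nsim unused (matches the generic).
#' @param seed optional integer seed (initial state, conductance split,
#'   reset noise).
#' @param Iapp applied current to each pre-synaptic neuron (nA).
#' @param duration simulated time (ms).
#' @param N neurons per population.
#' @param split conductance-split rule, see
#'   [build_population_pathway()].
#' @param stim_start current onset (ms).
#' @param ... passed on to [simulate_network()].
#' @return A `glif_sim` with attribute `pre` / `post` index vectors.
#' @export
simulate.fsa_pathway <- function(object, nsim = 1, seed = NULL,
                                 Iapp = 20, duration = 2000, N = 1,
                                 split = "normalized", stim_start = 0,
                                 ...) {
  if (!is.null(seed)) set.seed(seed)
  net <- build_population_pathway(object, N = N, split = split)
  stim <- stim_step(seq_len(N), Iapp, t_start = stim_start)
  sim <- simulate_network(net, stim, duration = duration, ...)
  attr(sim, "pre") <- seq_len(N)
  attr(sim, "post") <- N + seq_len(N)
  sim
}

#' @export
plot.fsa_pathway <- function(x, Iapp = NULL, ...) {
  if (is.null(Iapp))
    Iapp <- seq(0, x$ctx$Gmem * x$ctx$R, length.out = 41)[-1]
  fi <- fi_curve(x$pre, Iapp)
  graphics::matplot(fi$Iapp, cbind(fi$f_exact, fi$f_approx, fi$f_lower,
                                   fi$f_upper),
                    type = "l", lty = c(1, 2, 3, 3),
                    col = c("black", "blue", "grey40", "grey40"),
                    xlab = "applied current (nA)",
                    ylab = "steady-state frequency (kHz)", ...)
  graphics::legend("topleft", c("exact", "linear approx", "bounds"),
                   lty = c(1, 2, 3),
                   col = c("black", "blue", "grey40"), bty = "n")
  invisible(fi)
}
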