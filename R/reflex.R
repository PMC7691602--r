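# Closed-loop neuromechanical demonstration: a single-joint plant with an
# antagonist muscle pair, a stretch-encoding sensory node, a designed
# reflex pathway (non-spiking, or spiking with N neurons per node), and
# muscle-force decoding.
#
# The plant is deliberately simple and fully documented here: linear
# first-order muscle activation, linear passive muscle stiffness (tension
# only), and a damped rotational joint.  It stands in for a detailed
# musculoskeletal model; only ordinal comparisons between scenarios are
# meaningful.

#' Plant parameters for the stretch-reflex demonstration
#'
#' Units: time ms, angle rad, force and torque in arbitrary consistent
#' units (the decoding/encoding gains absorb the scale).
#'
#' @param inertia joint rotational inertia.
#' @param damping viscous joint damping.
#' @param moment_arm muscle moment arm (both muscles).
#' @param k_passive passive muscle stiffness (force per unit stretch;
#'   tension only).
#' @param F_active maximum active muscle force.
#' @param tau_act muscle activation time constant (ms).
#' @param k_enc stretch-encoding gain (nA per unit flexor stretch); the
#'   encoded current is clipped to the pathway's calibrated input range
#'   \eqn{[0, G_{mem} R]}.
#' @return An object of class `plant_params`.
#' @export
plant_params <- function(inertia = 63000, damping = 1500, moment_arm = 1,
                         k_passive = 10, F_active = 7, tau_act = 20,
                         k_enc = 40) {
  structure(list(inertia = check_positive(inertia, "inertia"),
                 damping = check_nonneg(damping, "damping"),
                 moment_arm = check_positive(moment_arm, "moment_arm"),
                 k_passive = check_nonneg(k_passive, "k_passive"),
                 F_active = check_positive(F_active, "F_active"),
                 tau_act = check_positive(tau_act, "tau_act"),
                 k_enc = check_positive(k_enc, "k_enc")),
            class = "plant_params")
}

#' Encode muscle stretch as applied current
#'
#' Affine map clipped to the pathway's calibrated input range:
#' \eqn{I_{app} = \mathrm{clip}(k_{enc}\,s, 0, G_{mem}R)} for stretch
#' `s`, so the sensory node operates within \eqn{[0, F_{max}]}.
#'
#' @param stretch muscle stretch (length above rest); vectorized.
#' @param plant a [plant_params()].
#' @param Gmem,R sensory-neuron leak conductance (uS) and operating
#'   range (mV).
#' @return Applied current in nA.
#' @export
encode_stretch <- function(stretch, plant, Gmem = 1, R = 20) {
  pmin(pmax(plant$k_enc * stretch, 0), Gmem * R)
}

#' Decode pathway output to muscle activation
#'
#' Normalizes the pathway's activation to \eqn{[0, 1]}: spiking
#' frequency over `Fmax`, or non-spiking depolarization over `R`.  (The
#' muscle's first-order activation dynamics supply the low-pass
#' filtering.)
#'
#' @param x pathway output: frequency (kHz) or depolarization (mV).
#' @param scale an [activation_scale()].
#' @param type `"spiking"` or `"nonspiking"`.
#' @return Activation command in `[0, 1]`.
#' @export
decode_activation <- function(x, scale, type = c("spiking",
                                                 "nonspiking")) {
  type <- match.arg(type)
  a <- if (type == "spiking") x / scale$Fmax else x / scale$R
  pmin(pmax(a, 0), 1)
}

reflex_network <- function(kind, design, N, tau_mem_bar_ns) {
  if (kind == "spiking") {
    build_population_pathway(design, N = N, split = "normalized")
  } else {
    ctx <- design$ctx
    Gbar <- design$Gbar_max
    neurons <- data.frame(
      type = "nonspiking",
      Cmem = c(tau_mem_bar_ns * ctx$Gmem,
               tau_mem_bar_ns * (ctx$Gmem + Gbar)),
      Gmem = ctx$Gmem, Ibias = 0,
      theta0 = NA_real_, tau_theta = NA_real_, m = NA_real_)
    synapses <- data.frame(pre = 1, post = 2, type = "graded",
                           Gmax = Gbar, tau_s = NA_real_, Es = design$Es,
                           R = ctx$R)
    glif_network(neurons, synapses)
  }
}

#' Run the four stretch-reflex scenarios
#'
#' Simulates a single-joint plant in which an extensor activation pulse
#' stretches the flexor; the flexor's stretch is encoded as current into
#' a reflex pathway whose output activates the flexor to resist.  Four
#' configurations are run: (1) open loop (flexor develops only passive
#' tension); (2) closed loop with a single spiking neuron per node;
#' (3) closed loop with populations of `N` spiking neurons per node;
#' (4) closed loop with non-spiking neurons and a graded synapse.
#'
#' The neural and plant systems are co-simulated with a zero-order-hold
#' coupling at `control_dt`: stretch is encoded, the network advances one
#' control interval, and its decoded output drives the flexor's
#' activation dynamics.
#'
#' @param m threshold-voltage proportionality of the pathway design (0
#'   for no frequency transient, negative for a slow rising transient).
#' @param N population size for scenario 3.
#' @param plant a [plant_params()].
#' @param duration simulated time (ms).
#' @param pulse extensor activation pulse interval `c(on, off)` (ms).
#' @param tau_mem_bar non-spiking analog membrane time constant (ms) used
#'   both for the `m != 0` design and for the non-spiking pathway; for
#'   `m = 0` the non-spiking pathway uses a short 10 ms time constant
#'   (the spiking `m = 0` design has no frequency transient to match).
#' @param reset_noise_sd Gaussian reset-noise sd (mV) applied to the
#'   spiking scenarios, decorrelating neurons within a population.
#' @param control_dt neural/mechanical coupling interval (ms).
#' @param seed integer seed.
#' @param scenarios subset of `1:4` to run.
#' @return List of class `reflex_result`: per-scenario trajectory data
#'   frames (`time`, `phi`, `omega`, `a_ext`, `a_flex`, `F_ext`,
#'   `F_flex`, `u_flex`, `Iapp`) and a `summary` data frame (peak and
#'   final angle, steady-state force fluctuation).
#' @export
run_reflex_scenarios <- function(m = 0, N = 10, plant = plant_params(),
                                 duration = 3500, pulse = c(250, 2500),
                                 tau_mem_bar = 500,
                                 reset_noise_sd = 0.1, control_dt = 1,
                                 seed = 1, scenarios = 1:4) {
  design <- if (m == 0) design_pathway(k_syn = 1, Es = 160, m = 0)
            else design_pathway(k_syn = 1, Es = 160, m = m,
                                tau_mem_bar = tau_mem_bar)
  scale <- activation_scale(R = design$ctx$R, Fmax = design$ctx$Fmax)
  kinds <- list(`1` = "open", `2` = "spiking", `3` = "spiking",
                `4` = "nonspiking")
  Ns <- c(0, 1, N, 0)
  out <- list()
  for (sc in scenarios) {
    set.seed(seed + sc)
    kind <- kinds[[as.character(sc)]]
    out[[paste0("case", sc)]] <- run_reflex_one(
      kind, design, Ns[sc], plant, duration, pulse,
      if (m == 0) 10 else tau_mem_bar, scale,
      if (kind == "spiking") reset_noise_sd else 0, control_dt)
  }
  summary <- do.call(rbind, lapply(names(out), function(nm) {
    tr <- out[[nm]]
    hold <- min(500, 0.4 * (pulse[2] - pulse[1]))
    tail_win <- tr$time >= pulse[2] - hold & tr$time <= pulse[2]
    data.frame(case = nm,
               peak_angle = max(tr$phi),
               final_angle = tr$phi[nrow(tr)],
               hold_angle = mean(tr$phi[tail_win]),
               force_fluct = if (any(tail_win))
                 sd(tr$F_flex[tail_win]) else NA_real_)
  }))
  structure(c(out, list(summary = summary, m = m)),
            class = "reflex_result")
}

#' @export
print.reflex_result <- function(x, ...) {
  cat(sprintf("stretch-reflex scenarios (m = %g)\n", x$m))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

run_reflex_one <- function(kind, design, N, plant, duration, pulse,
                           tau_mem_bar_ns, scale, reset_noise_sd,
                           control_dt) {
  ctx <- design$ctx
  net <- if (kind == "open") NULL
         else reflex_network(kind, design, N, tau_mem_bar_ns)
  state <- if (!is.null(net)) initialize_state(net) else NULL
  dt_net <- if (!is.null(net)) auto_timestep(net) else NA
  # make the coupling interval an exact multiple of the network step
  if (!is.null(net)) {
    chunk_steps <- max(1L, round(control_dt / dt_net))
    control_dt <- chunk_steps * dt_net
  }
  n_sens <- if (kind == "spiking") N else if (kind == "nonspiking") 1
            else 0
  motor_idx <- if (kind == "spiking") N + seq_len(N)
               else if (kind == "nonspiking") 2 else integer()

  nstep <- ceiling(duration / control_dt)
  tr <- data.frame(time = numeric(nstep), phi = 0, omega = 0, a_ext = 0,
                   a_flex = 0, F_ext = 0, F_flex = 0, u_flex = 0,
                   Iapp = 0)
  phi <- 0; omega <- 0; a_ext <- 0; a_flex <- 0
  # per-motor-neuron zero-order-hold instantaneous frequency
  last_spike <- rep(NA_real_, length(motor_idx))
  last_f <- rep(0, length(motor_idx))

  for (k in seq_len(nstep)) {
    t <- (k - 1) * control_dt
    stretch_flex <- plant$moment_arm * phi
    Iapp <- encode_stretch(stretch_flex, plant, ctx$Gmem, ctx$R)

    u_flex <- 0
    if (kind == "spiking") {
      stim <- stim_step(seq_len(n_sens), Iapp)
      sim <- simulate_network(net, stim, duration = control_dt,
                              dt = dt_net, init = state,
                              reset_noise_sd = reset_noise_sd,
                              record_every = chunk_steps, t_start = t)
      state <- sim$state
      for (j in seq_along(motor_idx)) {
        st <- sim$spikes[[motor_idx[j]]]
        for (s in st) {
          if (!is.na(last_spike[j])) last_f[j] <- 1 / (s - last_spike[j])
          last_spike[j] <- s
        }
      }
      u_flex <- mean(decode_activation(last_f, scale, "spiking"))
    } else if (kind == "nonspiking") {
      stim <- stim_step(1, Iapp)
      sim <- simulate_network(net, stim, duration = control_dt,
                              dt = dt_net, init = state,
                              record_every = chunk_steps, t_start = t)
      state <- sim$state
      u_flex <- decode_activation(state$U[2], scale, "nonspiking")
    }

    u_ext <- if (t >= pulse[1] && t < pulse[2]) 1 else 0
    a_ext <- a_ext + control_dt * (u_ext - a_ext) / plant$tau_act
    a_flex <- a_flex + control_dt * (u_flex - a_flex) / plant$tau_act

    F_ext <- a_ext * plant$F_active +
      plant$k_passive * max(-plant$moment_arm * phi, 0)
    F_flex <- a_flex * plant$F_active +
      plant$k_passive * max(plant$moment_arm * phi, 0)
    torque <- plant$moment_arm * (F_ext - F_flex) - plant$damping * omega
    omega <- omega + control_dt * torque / plant$inertia
    phi <- phi + control_dt * omega

    tr[k, ] <- c(t + control_dt, phi, omega, a_ext, a_flex, F_ext,
                 F_flex, u_flex, Iapp)
  }
  tr
}
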