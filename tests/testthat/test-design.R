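# The FSA design equations and the full pathway designer.

test_that("bias current design reproduces both worked examples", {
  expect_equal(design_bias_current(1, 1, 0), 0.5)
  expect_equal(round(design_bias_current(1, 1, -5), 3), 0.143)
  expect_equal(design_bias_current(1, 1, -5), 1 / 7)
  # equals Gmem * theta_star / 2 under the explicit approximation
  expect_equal(design_bias_current(1, 1, -5),
               1 * theta_star_approx(1, -5) / 2)
})

test_that("membrane time constant design reproduces both examples", {
  expect_equal(design_membrane_tau(20, 0.1, 1, 0), 200)
  expect_equal(design_membrane_tau(20, 0.1, 1, -5), 700)
  expect_equal(design_membrane_tau(20, 0.2, 1, 0), 100)
})

test_that("threshold time constant maps the intended transient", {
  expect_equal(design_theta_tau(500, -5), 1750)
  expect_equal(design_theta_tau(300, 0), 300)
  # roundtrip: the effective transient constant equals tau_mem_bar
  tau_theta <- design_theta_tau(500, -5)
  B <- 1 / (1 - (-5) / 2)
  expect_equal(tau_theta * B, 500)
})

test_that("synaptic decay constant honors the linearity budget", {
  expect_equal(round(design_synapse_tau(0.1, 0.01), 2), 2.17)
  expect_equal(design_synapse_tau(1, exp(-1)), 1)
  expect_lt(design_synapse_tau(0.1, 0.001), design_synapse_tau(0.1, 0.01))
  # the budget is met exactly at Fmax
  tau_s <- design_synapse_tau(0.1, 0.01)
  expect_equal(delta_nonlinearity(0.1, tau_s), 0.01)
})

test_that("conductance design from Gavg inverts the averaging relation", {
  Gmax <- design_gmax_from_gavg(0.1429, 2.17, 0.1, 0.01)
  expect_equal(Gmax, 0.1429 / (2.17 * 0.1 * 0.99))
  # roundtrip with average_conductance at f = Fmax
  tau_s <- design_synapse_tau(0.1, 0.01)
  G <- design_gmax_from_gavg(0.2, tau_s, 0.1, 0.01)
  expect_equal(average_conductance(G, tau_s, 0.1), 0.2,
               tolerance = 1e-6)
  expect_equal(design_gmax_from_gavg(0.2, 2, 0.1, 0),
               0.2 / (2 * 0.1))
})

test_that("gain-based conductance design reproduces Gmax = 0.658 uS", {
  expect_equal(round(design_gmax_from_gain(1, 20, 160, 2.17, 0.1), 3),
               0.658)
  expect_equal(design_gmax_from_gain(0, 20, 160, 2.17, 0.1), 0)
  expect_lt(design_gmax_from_gain(1, 20, 1e7, 2.17, 0.1), 1e-5)
  expect_error(design_gmax_from_gain(1, 20, 20, 2.17, 0.1), "singular")
  expect_error(design_gmax_from_gain(1, 20, 10, 2.17, 0.1),
               "Es > k_syn")
})

test_that("graded conductance design and its spiking consistency", {
  expect_equal(design_nonspiking_gmax(1, 20, 160), 1 / 7)
  expect_equal(round(design_nonspiking_gmax(1, 20, 160), 4), 0.1429)
  expect_equal(design_nonspiking_gmax(0, 20, 160), 0)
  # spiking design is the graded design divided by tau_s * Fmax
  expect_equal(design_gmax_from_gain(1, 20, 160, 2.17, 0.1),
               design_nonspiking_gmax(1, 20, 160) / (2.17 * 0.1))
  # inhibitory pathway uses the same algebra
  expect_gt(design_nonspiking_gmax(-1, 20, -60), 0)
})

test_that("the full designer reproduces worked example 1 (m = 0)", {
  d <- example_design_m0()
  expect_equal(d$Ibias, 0.5)
  expect_equal(d$tau_mem, 200)
  expect_equal(round(d$tau_s, 2), 2.17)
  expect_equal(round(d$Gmax, 3), 0.658)
  expect_equal(d$pre$Cmem, 200)
  # post-synaptic capacitance includes the design-point conductance load
  expect_equal(d$post$Cmem, 200 * (1 + 1 / 7))
})

test_that("the full designer reproduces worked example 2 (m = -5)", {
  d <- example_design_m5()
  expect_equal(d$tau_theta, 1750)
  expect_equal(round(d$Ibias, 3), 0.143)
  expect_equal(d$tau_mem, 700)
  expect_equal(round(d$tau_s, 2), 2.17)
  expect_equal(round(d$Gmax, 3), 0.658)
})

test_that("designer validates inputs and degenerate gains", {
  expect_error(design_pathway(m = 2), "m")
  expect_error(design_pathway(m = -5), "tau_mem_bar")
  d0 <- design_pathway(k_syn = 0, Es = 160, m = 0)
  expect_equal(d0$Gmax, 0)
  d <- example_design_m0()
  expect_true(all(coef(d) > 0))
})

test_that("designed neuron spans [0, Fmax] over the calibrated range", {
  d <- example_design_m0()
  net <- build_population_pathway(d, N = 1)
  # at Iapp = Gmem * R the neuron fires at ~Fmax
  sim <- simulate_network(net, stim_step(1, 20), duration = 1500,
                          seed = 5)
  f <- steady_state_frequency(sim$spikes[[1]], 1500)
  expect_equal(f, d$ctx$Fmax, tolerance = 0.01)
  # at Iapp = 0 the bias alone is subthreshold: no spikes
  sim0 <- simulate_network(net, NULL, duration = 1500, seed = 5)
  expect_length(sim0$spikes[[1]], 0)
})

test_that("model object methods are coherent", {
  d <- example_design_m0()
  expect_output(print(d), "gain k_syn = 1")
  pred <- predict(d, Iapp = c(5, 10, 20))
  expect_equal(pred$f_intended, c(0.025, 0.05, 0.1))
  # analytic post frequency tracks the intended value closely
  expect_true(all(abs(pred$f_post / pred$f_intended - 1) < 0.02))
  expect_named(coef(d), c("Ibias", "tau_mem", "tau_theta", "tau_s",
                          "Gmax", "Gbar_max", "Cmem_pre", "Cmem_post"))
})
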