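# Network assembly and the forward-Euler integrator.

test_that("population pathway wiring follows the N^2 rule", {
  d <- example_design_m0()
  net1 <- build_population_pathway(d, N = 1)
  expect_equal(nrow(net1$synapses), 1)
  expect_equal(net1$synapses$Gmax, d$Gmax)
  net10 <- build_population_pathway(d, N = 10, seed = 3)
  expect_equal(nrow(net10$neurons), 20)
  expect_equal(nrow(net10$synapses), 100)
  # normalized split: each post neuron's incoming conductances sum to Gmax
  sums <- tapply(net10$synapses$Gmax, net10$synapses$post, sum)
  expect_equal(as.vector(sums), rep(d$Gmax, 10), tolerance = 1e-12)
  # raw_uniform split: totals vary but their mean is near Gmax
  netr <- build_population_pathway(d, N = 10, seed = 3,
                                   split = "raw_uniform")
  sums_r <- tapply(netr$synapses$Gmax, netr$synapses$post, sum)
  expect_gt(sd(sums_r), 0)
  expect_equal(mean(sums_r), d$Gmax, tolerance = 0.2)
})

test_that("automatic time step follows the 1e-4 min-tau rule", {
  d <- example_design_m0()
  net <- build_population_pathway(d, N = 1)
  expect_equal(auto_timestep(net), 0.02)
  # a faster neuron sets the step
  net$neurons$Cmem[1] <- 100
  expect_equal(auto_timestep(net), 0.01)
})

test_that("initial states are seeded, bounded, and typed", {
  d <- example_design_m0()
  net <- build_population_pathway(d, N = 5, seed = 1)
  s1 <- initialize_state(net, seed = 9)
  s2 <- initialize_state(net, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(s1$U >= 0 & s1$U <= net$neurons$theta0))
  expect_equal(s1$theta, net$neurons$theta0)
  expect_equal(s1$Gs, numeric(nrow(net$synapses)))
  # non-spiking neurons initialize at rest
  ns <- glif_network(data.frame(type = "nonspiking", Cmem = 100,
                                Gmem = 1))
  expect_equal(initialize_state(ns, seed = 1)$U, 0)
})

test_that("simulation is bit-reproducible for a fixed seed", {
  d <- example_design_m0()
  a <- simulate(d, seed = 123, Iapp = 20, duration = 400, N = 3,
                reset_noise_sd = 0.1)
  b <- simulate(d, seed = 123, Iapp = 20, duration = 400, N = 3,
                reset_noise_sd = 0.1)
  expect_identical(a$U, b$U)
  expect_identical(a$spikes, b$spikes)
})

test_that("spike times are increasing and conductances stay bounded", {
  d <- example_design_m0()
  sim <- simulate(d, seed = 4, Iapp = 20, duration = 800, N = 2,
                  record_gs = TRUE)
  for (st in sim$spikes) expect_true(all(diff(st) > 0))
  expect_true(all(sim$Gs >= 0))
  expect_true(all(sim$Gs <= max(sim$net$synapses$Gmax) + 1e-12))
})

test_that("a non-spiking neuron tracks the closed-form step response", {
  net <- glif_network(data.frame(type = "nonspiking", Cmem = 200,
                                 Gmem = 1))
  sim <- simulate_network(net, stim_step(1, 10), duration = 1000,
                          dt = 0.02)
  expect_equal(sim$U[, 1],
               nonspiking_transient(sim$time, 10, 200),
               tolerance = 1e-3)
})

test_that("the simulated f-I point matches the analytic frequency", {
  d <- example_design_m0()
  net <- build_population_pathway(d, N = 1)
  sim <- simulate_network(net, stim_step(1, 20), duration = 1500,
                          seed = 2)
  f_sim <- steady_state_frequency(sim$spikes[[1]], 1500)
  f_th <- spiking_frequency(20.5, 1, 200)
  expect_equal(f_sim, f_th, tolerance = 0.01)
})

test_that("halving the step shows first-order convergence", {
  d <- example_design_m0()
  net <- build_population_pathway(d, N = 1)
  f_at <- function(dt) {
    sim <- simulate_network(net, stim_step(1, 20), duration = 1000,
                            dt = dt, init = rest_state(net))
    steady_state_frequency(sim$spikes[[1]], 1000)
  }
  f1 <- f_at(0.08); f2 <- f_at(0.04); f3 <- f_at(0.02)
  expect_lt(abs(f3 - f2), abs(f2 - f1))
})

test_that("the instability guard stops a divergent integration", {
  # dt far above the stability limit of this fast membrane
  net <- glif_network(data.frame(type = "nonspiking", Cmem = 0.01,
                                 Gmem = 1))
  expect_error(
    simulate_network(net, stim_step(1, 10), duration = 50, dt = 1,
                     init = list(U = 0, theta = 0, Gs = numeric(0))),
    "instability")
})

test_that("network validation names the offending field", {
  nr <- data.frame(type = "glif", Cmem = 200, Gmem = 1, Ibias = 0,
                   theta0 = 1, tau_theta = 100, m = 3)
  expect_error(glif_network(nr), "`m`")
  nr$m <- 0
  sy <- data.frame(pre = 1, post = 5, type = "spiking", Gmax = 0.1,
                   tau_s = 2, Es = 160)
  expect_error(glif_network(nr, sy), "`post`")
})

test_that("transmission drops occur at N = 1 and vanish at N = 10", {
  # marginal per-pulse charge plus reset noise: the single post neuron
  # occasionally misses a pre spike, visible as ISIs well above the
  # median; a population's smoother drive removes the artifact
  d <- example_design_m0()
  drops1 <- vapply(1:3, function(seed) {
    sim <- simulate(d, seed = seed, Iapp = 20, duration = 3000, N = 1,
                    reset_noise_sd = 0.1)
    st <- sim$spikes[[2]]
    count_frequency_drops(st[st > 500])
  }, integer(1))
  expect_true(all(drops1 > 0))
  sim10 <- simulate(d, seed = 1, Iapp = 20, duration = 3000, N = 10,
                    reset_noise_sd = 0.1)
  drops10 <- mean(vapply(attr(sim10, "post"), function(i) {
    st <- sim10$spikes[[i]]
    count_frequency_drops(st[st > 500])
  }, integer(1)))
  expect_lt(drops10, mean(drops1) / 2)
})
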