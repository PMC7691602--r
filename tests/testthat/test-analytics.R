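# Closed-form frequency machinery and the implicit spike-time threshold.

test_that("steady-state threshold is affine in the target voltage", {
  expect_equal(steady_state_threshold(1, 0, 37), 1)
  expect_equal(steady_state_threshold(1, -5, 20.5), -101.5)
  expect_equal(steady_state_threshold(1, -5, 0), 1)
})

test_that("spiking frequency matches its closed form and conventions", {
  # ln collapses to -1 at theta/U = 1 - 1/e
  expect_equal(spiking_frequency(1, 1 - exp(-1), 200), 1 / 200)
  expect_equal(spiking_frequency(20.5, 1, 200),
               -1 / (200 * log(1 - 1 / 20.5)))
  expect_equal(round(spiking_frequency(20.5, 1, 200), 5), 0.09998)
  # subthreshold target voltage: frequency defined as 0
  expect_equal(spiking_frequency(0.5, 1, 200), 0)
  expect_error(spiking_frequency(10, -1, 200), "invalid threshold")
})

test_that("implicit spike-time threshold solves and has the right limits", {
  p <- glif_neuron(Cmem = 700, Gmem = 1, Ibias = 0.143, theta0 = 1,
                   tau_theta = 1750, m = -5)
  # m = 0 short-circuits to theta0
  p0 <- glif_neuron(Cmem = 200, Gmem = 1, theta0 = 1, m = 0)
  expect_identical(solve_theta_star(20.5, p0, 200), 1)
  root <- solve_theta_star(20.5, p, 700)
  expect_gt(root, 0); expect_lt(root, 20.5)
  expect_equal(root, theta_star_approx(1, -5), tolerance = 0.01)
  # the two printed branches agree in the tau_theta -> tau_mem limit
  p_eq <- glif_neuron(Cmem = 700, Gmem = 1, theta0 = 1,
                      tau_theta = 700, m = -5)
  p_near <- glif_neuron(Cmem = 700, Gmem = 1, theta0 = 1,
                        tau_theta = 700 * 1.001, m = -5)
  expect_equal(solve_theta_star(20.5, p_eq, 700),
               solve_theta_star(20.5, p_near, 700), tolerance = 1e-3)
  # just inside the branch switch the equal-tau form is used
  p_in <- glif_neuron(Cmem = 700, Gmem = 1, theta0 = 1,
                      tau_theta = 700 * (1 + 1e-8), m = -5)
  expect_identical(solve_theta_star(20.5, p_in, 700),
                   solve_theta_star(20.5, p_eq, 700))
  # adapting neuron with subthreshold steady state: no root
  p_ad <- glif_neuron(Cmem = 200, Gmem = 1, theta0 = 1,
                      tau_theta = 500, m = 1)
  expect_error(solve_theta_star(1.5, p_ad, 200), "cannot spike")
})

test_that("spike-time threshold approaches the explicit approximation", {
  p <- glif_neuron(Cmem = 700, Gmem = 1, Ibias = 0.143, theta0 = 1,
                   tau_theta = 1750, m = -5)
  U <- 5 * 2^(0:5)
  err <- vapply(U, function(u)
    abs(solve_theta_star(u, p, 700) - theta_star_approx(1, -5)),
    numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[length(err)], 1e-3)
})

test_that("explicit threshold approximation and its singularity", {
  expect_equal(theta_star_approx(1, 0), 1)
  expect_equal(theta_star_approx(1, -5), 1 / 3.5)
  expect_error(theta_star_approx(1, 2), "m")
  expect_error(theta_star_approx(1, 2.5), "m")
})

test_that("frequency bounds form a band of width 1/tau around the line", {
  b <- frequency_bounds(20, 1, 200, 1)
  expect_equal(b$upper - b$lower, 1 / 200)
  expect_equal((b$upper + b$lower) / 2,
               linear_frequency_approx(20, 1, 200, 1))
  expect_equal(c(b$lower, b$upper), c(0.0975, 0.1025))
  expect_equal(linear_frequency_approx(0, 1, 200, 1), 0)
  expect_equal(linear_frequency_approx(40, 1, 200, 1),
               2 * linear_frequency_approx(20, 1, 200, 1))
})

test_that("exact frequency lies within the bounds under the bias rule", {
  set.seed(31)
  for (i in 1:20) {
    m <- runif(1, -6, 0.5)   # keep the steady state suprathreshold
    theta0 <- runif(1, 0.5, 2)
    tau_mem <- runif(1, 100, 800)
    tau_theta <- runif(1, 200, 2500)
    Gmem <- 1
    ts_approx <- theta_star_approx(theta0, m)
    Ibias <- Gmem * theta0 / (2 - m)      # the Eq-21 bias rule
    p <- glif_neuron(Cmem = tau_mem * Gmem, Gmem = Gmem, Ibias = Ibias,
                     theta0 = theta0, tau_theta = tau_theta, m = m)
    Iapp <- runif(1, 5, 40) * theta0
    U_inf <- (Iapp + Ibias) / Gmem
    ts <- solve_theta_star(U_inf, p, tau_mem)
    f <- spiking_frequency(U_inf, ts, tau_mem)
    b <- frequency_bounds(Iapp, Gmem, tau_mem, ts)
    expect_gte(f, b$lower); expect_lte(f, b$upper)
  }
})

test_that("activation maps are inverse linear scalings", {
  sc <- activation_scale(R = 20, Fmax = 0.1)
  expect_equal(activation_to_frequency(20, sc), 0.1)
  expect_equal(activation_to_frequency(0, sc), 0)
  expect_equal(activation_to_frequency(10, sc), 0.05)
  expect_equal(frequency_to_activation(activation_to_frequency(7, sc),
                                       sc), 7)
})

test_that("threshold transient interpolates theta0 -> theta_star_inf", {
  ts_inf <- theta_star_approx(1, -5)
  expect_equal(threshold_transient(0, 1, ts_inf, 1750, -5), 1)
  expect_equal(threshold_transient(1e9, 1, ts_inf, 1750, -5), ts_inf)
  # effective time constant is tau_theta * B = 500 ms here
  th <- threshold_transient(500, 1, ts_inf, 1750, -5)
  expect_equal((th - ts_inf) / (1 - ts_inf), exp(-1))
})

test_that("average conductance matches a numerical average of the decay", {
  expect_equal(round(average_conductance(1, 2.17, 0.1), 4), 0.2148)
  # numerical cross-check: average of Gmax e^{-t/tau} over one period
  for (f in c(0.02, 0.1, 0.4)) {
    Tsp <- 1 / f
    g_num <- stats::integrate(function(t) exp(-t / 2.17), 0,
                              Tsp)$value / Tsp
    expect_equal(average_conductance(1, 2.17, f), g_num,
                 tolerance = 1e-7)
  }
  # saturation and low-rate limits
  expect_equal(average_conductance(1, 2.17, 1e6), 1, tolerance = 1e-3)
  expect_equal(average_conductance(1, 2.17, 1e-4),
               2.17 * 1e-4, tolerance = 1e-6)
  expect_equal(average_conductance(1, 2.17, 0), 0)
  # strictly increasing in f and bounded by Gmax
  f <- seq(0.005, 2, by = 0.005)
  g <- average_conductance(0.658, 2.17, f)
  expect_true(all(diff(g) > 0))
  expect_true(all(g < 0.658))
})

test_that("nonlinearity term delta has its printed value and limits", {
  expect_equal(delta_nonlinearity(0.1, 2.17), 0.01, tolerance = 0.01)
  expect_equal(delta_nonlinearity(1 / log(2), 1), 0.5)
  expect_lt(delta_nonlinearity(0.001, 2.17), 1e-100)
  expect_error(delta_nonlinearity(0, 2.17), "positive")
})

test_that("f-I curve tabulates and exports", {
  p <- glif_neuron(Cmem = 200, Gmem = 1, Ibias = 0.5, theta0 = 1, m = 0)
  fi <- fi_curve(p, c(5, 10, 20))
  expect_equal(fi$theta_star, rep(1, 3))
  expect_true(all(fi$f_exact >= fi$f_lower & fi$f_exact <= fi$f_upper))
  path <- tempfile(fileext = ".csv")
  fi_curve(p, c(5, 10, 20), file = path)
  back <- read.csv(path)
  expect_equal(back$f_exact, fi$f_exact, tolerance = 1e-12)
})
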