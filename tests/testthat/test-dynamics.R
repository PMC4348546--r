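test_that("an isolated cell relaxes to its production/degradation balance", {
  tg <- make_grid(1, 1)
  sim <- simulate_flux("slow", tg, model_params(alpha_a = 1, beta_a = 1),
                       response_quadratic(), flux_state(tg, a = 0),
                       integrator_options(t_max = 60))
  expect_equal(sim$status, "converged")
  expect_equal(sim$final_state$a, 1, tolerance = 1e-7)
})

test_that("integration is deterministic", {
  tg <- make_line(4)
  pars <- model_params(alpha_a = c(1, 0.2, 0.2, 0.2), beta_a = 0.5, mu = 0.2,
                       lambda = 0.5)
  init <- random_state(tg, seed = 42, scale = 0.5)
  opts <- integrator_options(t_max = 30)
  s1 <- simulate_flux("slow", tg, pars, response_quadratic(), init, opts)
  s2 <- simulate_flux("slow", tg, pars, response_quadratic(), init, opts)
  expect_identical(s1$status, s2$status)
  expect_identical(s1$final_state, s2$final_state)
  expect_identical(s1$trajectory, s2$trajectory)
})

test_that("quadratic feedback with strong PIN capacity escapes in finite time", {
  sim <- run_blowup()
  expect_equal(sim$status, "diverged")
  expect_true(is.finite(sim$escape_time))
  expect_lte(sim$escape_time, 5)

  # escape-time estimate is robust: 100x larger threshold, 10x tighter tols
  d_thr <- run_blowup(threshold = 1e8)
  expect_lt(abs(d_thr$escape_time - sim$escape_time) / sim$escape_time, 0.05)
  d_tol <- run_blowup(rtol = 1e-11, atol = 1e-13)
  expect_lt(abs(d_tol$escape_time - sim$escape_time) / sim$escape_time, 0.05)
})

test_that("the same configuration with a bounded response is global", {
  bu <- blowup_setup()
  sim <- simulate_flux("slow", bu$tissue, bu$params,
                       response_hill(rho = 1, theta = 1, n = 2),
                       flux_state(bu$tissue, a = bu$init_a, p = bu$init_p),
                       integrator_options(t_max = 200))
  expect_true(sim$status %in% c("converged", "reached_t_max", "oscillating"))
  expect_true(is.na(sim$escape_time))
})

test_that("bounded responses never trigger the detector on random scenarios", {
  rf <- response_hill(rho = 1, theta = 0.5, n = 2)
  for (s in 1:25) {
    dims <- withr::with_seed(s, sample(2:4, 2, replace = TRUE))
    tg <- make_grid(dims[1], dims[2])
    pars <- withr::with_seed(s + 500, model_params(
      alpha_a = runif(tg$n_cells, 0.1, 2), beta_a = runif(1, 0.2, 2),
      mu = runif(1, 0.1, 1), lambda = runif(1, 0.5, 5),
      alpha_p = runif(1, 0.5, 5), beta_p = 1))
    init <- random_state(tg, seed = s, scale = 1)
    sim <- simulate_flux("slow", tg, pars, rf, init,
                         integrator_options(t_max = 20, rtol = 1e-6,
                                            atol = 1e-8, n_chunks = 10))
    expect_false(sim$status == "diverged")
  }
})

test_that("nonnegativity is preserved along trajectories", {
  tg <- make_grid(2, 3)
  pars <- model_params(alpha_a = 0.5, beta_a = 0.5, gamma_D = 0.1, mu = 0.3,
                       lambda = 1, rho0 = 0.05)
  for (variant in c("slow", "full")) {
    p2 <- pars
    if (variant == "slow") p2$gamma_D <- 0
    init <- random_state(tg, seed = 3, scale = 1)
    sim <- simulate_flux(variant, tg, p2, response_quadratic(), init,
                         integrator_options(t_max = 50, rtol = 1e-8))
    expect_gte(min(sim$trajectory), -1e-7)
  }
  ste <- random_state(tg, seed = 4, scale = 1, cytosolic = TRUE)
  sim <- simulate_flux("extended", tg, pars, response_quadratic(), ste,
                       integrator_options(t_max = 50))
  expect_gte(min(sim$trajectory), -1e-7)
})

test_that("convergence and oscillation detectors behave on constructed signals", {
  const_tail <- matrix(1, nrow = 50, ncol = 3)
  expect_false(detect_oscillation(const_tail))
  sine <- cbind(1 + 0.2 * sin(seq(0, 20 * pi, length.out = 200)), 2)
  expect_true(detect_oscillation(sine))
  drifting <- cbind(seq(0, 5, length.out = 200))
  expect_false(detect_oscillation(drifting))
  expect_error(detect_oscillation(matrix(1, 2, 1), window = 1), "window")
})

test_that("the standalone blow-up detector needs a super-linear signature", {
  tt <- seq(0, 1, length.out = 200)
  linear <- cbind(2e6 * tt)                     # crosses threshold, linear
  expect_null(detect_blowup(tt, linear, threshold = 1e6))
  hyper <- cbind(1 / (1.0005 - tt))             # escapes at t ~ 1.0005
  delta <- detect_blowup(tt, hyper, threshold = 100)
  expect_false(is.null(delta))
  expect_equal(delta, 1.0005, tolerance = 0.02)
  # monotone in threshold
  d2 <- detect_blowup(tt, hyper, threshold = 500)
  expect_gte(d2, delta - 1e-9)
})

test_that("cut-off runs stay clamped and never report divergence", {
  bu <- blowup_setup()
  init <- flux_state(bu$tissue, a = bu$init_a, p = bu$init_p)
  sim <- run_with_cutoff("slow", bu$tissue, bu$params, response_quadratic(),
                         init, integrator_options(t_max = 20), p_max = 1e3)
  expect_false(sim$status == "diverged")
  expect_lte(max(sim$final_state$p), 1e3 + 1e-6)

  # p_max = 0: active transport off, auxin relaxes to alpha/beta
  sim0 <- run_with_cutoff("slow", bu$tissue, bu$params, response_quadratic(),
                          init, integrator_options(t_max = 60), p_max = 0)
  expect_equal(sim0$final_state$a, c(1, 1), tolerance = 1e-6)

  # clamp inactive on a non-divergent configuration: same result as integrate
  tg <- make_line(3)
  pars <- model_params(alpha_a = 1, beta_a = 1, mu = 1, lambda = 0.1)
  init2 <- random_state(tg, seed = 6, scale = 0.3)
  a <- simulate_flux("slow", tg, pars, response_quadratic(), init2,
                     integrator_options(t_max = 40))
  b <- run_with_cutoff("slow", tg, pars, response_quadratic(), init2,
                       integrator_options(t_max = 40), p_max = 1e6)
  expect_equal(a$final_state$a, b$final_state$a, tolerance = 1e-8)
})

test_that("slow-fast comparison degenerates to solver noise when models coincide", {
  # one isolated cell, no diffusion: the extended model with P at its
  # quasi-steady value is exactly the slow model
  tg <- make_grid(1, 1)
  pars <- model_params(alpha_a = 1, beta_a = 1, mu = 0.5, lambda = 1)
  init <- flux_state(tg, a = 0.2)
  dev <- compare_slow_fast(tg, pars, response_quadratic(), init,
                           epsilons = 1, t_max = 20,
                           options = integrator_options(t_max = 20))
  expect_lt(dev$sup_dev, 1e-6)
})

test_that("slow-fast comparison refuses a non-convergent reference", {
  bu <- blowup_setup()
  init <- flux_state(bu$tissue, a = bu$init_a, p = bu$init_p)
  expect_error(
    compare_slow_fast(bu$tissue, bu$params, response_quadratic(), init,
                      epsilons = 0.1, t_max = 0.001,
                      options = integrator_options(t_max = 0.001)),
    "converge")
})
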