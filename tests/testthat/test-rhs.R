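test_that("flux laws are antisymmetric and match direct substitution", {
  expect_equal(diffusive_flux(2, 2, 5), 0)
  expect_equal(diffusive_flux(3, 1, 0.5), 1.0)
  expect_equal(active_flux(1, 1, 1, 1, 1), 0)
  expect_equal(active_flux(2, 1, 3, 0, 1), 6)
  expect_lte(active_flux(0, 2, 5, 3, 1.5), 0)  # no efflux from an empty cell

  draws <- withr::with_seed(5, matrix(runif(500, 0, 10), ncol = 5))
  for (r in seq_len(nrow(draws))) {
    v <- draws[r, ]
    expect_identical(diffusive_flux(v[1], v[2], v[5]),
                     -diffusive_flux(v[2], v[1], v[5]))
    expect_identical(active_flux(v[1], v[2], v[3], v[4], v[5]),
                     -active_flux(v[2], v[1], v[4], v[3], v[5]))
  }
})

test_that("full-model derivative matches a hand-computed two-cell case", {
  # V = (2, 4), S = 3, gamma_D = 0.5, gamma_A = 2, quadratic response:
  # J_12 = 0.5*(1.5-0.5) + 2*(1.5*0.4 - 0.5*0.1) = 1.6
  # da_1 = 1 - 0.1*1.5 - (3/2)*1.6  = -1.55
  # da_2 = 0.2 - 0.3*0.5 + (3/4)*1.6 = 1.25
  # dp_12 = 1.6^2 + 0.05 - 0.2*0.4 = 2.53 ; dp_21 = 0 + 0.05 - 0.02 = 0.03
  tg <- tissue_graph(rbind(c(1, 2)), volumes = c(2, 4), areas = 3)
  pars <- model_params(alpha_a = c(1, 0.2), beta_a = c(0.1, 0.3),
                       gamma_D = 0.5, gamma_A = 2, rho0 = 0.05, mu = 0.2)
  st <- flux_state(tg, a = c(1.5, 0.5), p = c(0.4, 0.1))
  d <- rhs_full(st, tg, pars, response_quadratic())
  expect_equal(d$a, c(-1.55, 1.25))
  expect_equal(d$p, c(2.53, 0.03))
})

test_that("the all-isolated configuration is an equilibrium", {
  tg <- make_grid(3, 3)
  # homogeneous balance a* = alpha/beta (the full model has diffusion, so the
  # all-isolated equilibrium needs a flat auxin profile there)
  beta <- withr::with_seed(3, runif(9, 0.5, 2))
  alpha <- 1.3 * beta
  pars <- model_params(alpha_a = alpha, beta_a = beta, rho0 = 0, mu = 0.3,
                       gamma_D = 0.2)
  e0 <- flux_state(tg, a = alpha / beta, p = 0)
  for (rf in list(response_quadratic(), response_hill())) {
    d <- rhs_full(e0, tg, pars, rf)
    expect_equal(max(abs(c(d$a, d$p))), 0)
    d <- rhs_slow(e0, tg, pars, rf)
    expect_equal(max(abs(c(d$a, d$p))), 0)
  }
})

test_that("transport conserves total auxin when synthesis and decay are off", {
  tg <- make_grid(3, 3, regular = FALSE, seed = 4)
  pars <- model_params(alpha_a = 0, beta_a = 0, gamma_D = 0.7, gamma_A = 1.3,
                       rho0 = 0.1, mu = 0.5)
  tgr <- make_grid(3, 3)
  for (s in 1:10) {
    st <- random_state(tg, seed = s, scale = 2)
    d <- rhs_full(st, tg, pars, response_quadratic())
    expect_equal(sum(tg$cells$volume * d$a), 0, tolerance = 1e-14)
    ste <- random_state(tg, seed = s + 100, scale = 2, cytosolic = TRUE)
    de <- rhs_extended(ste, tg, pars, response_quadratic())
    expect_equal(sum(tg$cells$volume * de$a), 0, tolerance = 1e-14)
    str <- random_state(tgr, seed = s, scale = 2)
    dr <- rhs_slow(str, tgr, pars, response_quadratic())
    expect_equal(sum(tgr$cells$volume * dr$a), 0, tolerance = 1e-14)
  }
})

test_that("extended-model derivative matches an independent evaluator", {
  # second, deliberately naive implementation: explicit loops over cells
  naive_extended <- function(st, tg, pars, rf) {
    n <- tg$n_cells
    pr <- tg$pairs
    area <- tg$edges$area[pr$edge]
    Jof <- function(k) {
      pars$gamma_D * (st$a[pr$i[k]] - st$a[pr$j[k]]) +
        pars$gamma_A * (st$a[pr$i[k]] * st$p[k] - st$a[pr$j[k]] * st$p[pr$rev[k]])
    }
    da <- dP <- numeric(n)
    dp <- numeric(nrow(pr))
    for (k in seq_len(nrow(pr))) {
      dp[k] <- pars$lambda * st$P[pr$i[k]] * rf_eval(rf, Jof(k)) -
        pars$mu * st$p[k]
    }
    for (i in seq_len(n)) {
      ks <- which(pr$i == i)
      flux <- sum(area[ks] * vapply(ks, Jof, 1))
      da[i] <- pars$alpha_a[i] - pars$beta_a[i] * st$a[i] -
        flux / tg$cells$volume[i]
      cyc <- sum(area[ks] * (pars$mu * st$p[ks] -
                               pars$lambda * st$P[i] *
                                 rf_eval(rf, vapply(ks, Jof, 1))))
      dP[i] <- pars$alpha_p - pars$beta_p * st$P[i] + cyc / tg$cells$volume[i]
    }
    list(a = da, P = dP, p = dp)
  }
  tg <- make_grid(3, 3, regular = FALSE, seed = 9)
  pars <- model_params(alpha_a = withr::with_seed(1, runif(9)),
                       beta_a = 0.4, gamma_D = 0.3, gamma_A = 1.1,
                       mu = 0.6, lambda = 0.8, alpha_p = 0.9, beta_p = 0.7)
  pars <- fluxcanal:::expand_params(pars, tg)
  for (s in 1:5) {
    st <- random_state(tg, seed = s, scale = 3, cytosolic = TRUE)
    got <- rhs_extended(st, tg, pars, response_quadratic())
    want <- naive_extended(st, tg, pars, response_quadratic())
    expect_equal(got$a, want$a, tolerance = 1e-13)
    expect_equal(got$P, want$P, tolerance = 1e-13)
    expect_equal(got$p, want$p, tolerance = 1e-13)
  }
})

test_that("per-cell PIN is conserved identically without production/decay", {
  tg <- make_grid(3, 3)
  pars <- model_params(alpha_a = 1, beta_a = 1, gamma_A = 1, mu = 0.5,
                       lambda = 2, alpha_p = 0, beta_p = 0)
  for (s in 1:20) {
    st <- random_state(tg, seed = s, scale = 2, cytosolic = TRUE)
    d <- rhs_extended(st, tg, pars, response_quadratic())
    dstate <- structure(list(a = d$a, P = d$P, p = d$p), class = "flux_state")
    # derivative of P_i + (1/V_i) sum S_ij p_ij, evaluated exactly
    drift <- d$P + fluxcanal:::surface_sum(d$p, tg)
    expect_true(all(abs(drift) == 0))
  }
})

test_that("total_cell_pin computes the membrane-weighted total", {
  tg <- make_line(3)
  st <- flux_state(tg, a = 1, p = 0, P = 1)
  expect_equal(total_cell_pin(st, tg), c(1, 1, 1))
  st2 <- flux_state(tg, a = 1, p = c(2, 0, 0, 0), P = 0)
  expect_equal(total_cell_pin(st2, tg, cells = 1), 2)
})

test_that("slow variant refuses non-regular tissues and isolated cells decouple", {
  tg_bad <- make_grid(2, 2, regular = FALSE, seed = 1)
  pars <- model_params(alpha_a = 1, beta_a = 1)
  st <- flux_state(tg_bad, a = 1, p = 0)
  expect_error(rhs_slow(st, tg_bad, pars, response_quadratic()), "regular")

  tg <- make_line(3)
  pars2 <- model_params(alpha_a = c(2, 1, 1), beta_a = c(0.5, 1, 1))
  # all faces incident to cell 1 empty: its auxin equation is the scalar law
  st2 <- flux_state(tg, a = c(0.3, 1, 2), p = c(0, 0.7, 0, 0.2))
  d <- rhs_slow(st2, tg, pars2, response_quadratic())
  expect_equal(d$a[1], 2 - 0.5 * 0.3)
})

test_that("state validation catches dimension and sign errors", {
  tg <- make_line(3)
  expect_error(flux_state(tg, a = c(-1, 1, 1)), "nonnegative")
  expect_error(flux_state(tg, a = c(Inf, 1, 1)), "finite")
  st <- flux_state(make_line(4), a = 1, p = 0)
  expect_error(rhs_slow(st, tg, model_params(1, 1), response_quadratic()),
               "dimensions")
  ste <- flux_state(tg, a = 1, p = 0)  # no P
  expect_error(rhs_extended(ste, tg, model_params(1, 1), response_quadratic()),
               "cytosolic")
})
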