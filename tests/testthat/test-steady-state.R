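test_that("orientation extraction follows the complementarity rule", {
  tg <- make_line(2)
  # all PIN zero: empty orientation, everything isolated
  o0 <- extract_orientation(flux_state(tg, a = 1, p = 0), tg)
  expect_equal(nrow(o0$edges), 0)
  expect_equal(o0$isolated, 1:2)

  o1 <- extract_orientation(flux_state(tg, a = c(2, 1), p = c(0.7, 0)), tg)
  expect_equal(o1$edges$from, 1)
  expect_equal(o1$edges$to, 2)
  expect_equal(o1$edges$p, 0.7)
  expect_equal(o1$edges$J, 2 * 0.7)
  expect_equal(length(o1$isolated), 0)

  # both faces loaded: not a slow-model equilibrium orientation
  expect_error(extract_orientation(flux_state(tg, a = 1, p = c(1, 1)), tg),
               "1~2")
})

test_that("topology classification implements the necessary conditions", {
  cyc <- orientation(rbind(c(1, 2), c(2, 3), c(3, 1)), 3)
  rep_cyc <- classify_topology(cyc)
  expect_true(rep_cyc$has_cycle)
  expect_equal(length(rep_cyc$sinks), 0)
  expect_equal(rep_cyc$verdict, "certified_unstable")

  path <- classify_topology(orientation(rbind(c(1, 2), c(2, 3)), 3))
  expect_equal(path$sinks, 3)
  expect_equal(path$sources, 1)
  expect_true(path$is_sink_rooted_forest)
  expect_equal(path$verdict, "necessary_conditions_met")

  fork <- classify_topology(orientation(rbind(c(1, 2), c(1, 3)), 3))
  expect_equal(fork$verdict, "certified_unstable")  # out-degree 2
  expect_false(fork$is_sink_rooted_forest)

  # sink-rooted forests have exactly one sink per component
  forest <- classify_topology(orientation(rbind(c(1, 2), c(3, 2), c(5, 4)), 6))
  expect_true(forest$is_sink_rooted_forest)
  comp <- igraph::components(
    fluxcanal:::as_igraph_orientation(orientation(rbind(c(1, 2), c(3, 2), c(5, 4)), 6)))
  expect_equal(length(forest$sinks), 2)
})

test_that("the one-cell linearization is the scalar decay rate", {
  tg <- make_grid(1, 1)
  pars <- model_params(alpha_a = 2, beta_a = 0.7)
  eq <- flux_state(tg, a = 2 / 0.7)
  st <- jacobian_stability("slow", tg, pars, response_quadratic(), eq)
  expect_equal(Re(st$eigenvalues), -0.7)
  expect_equal(st$classification, "stable")
})

test_that("non-equilibria are rejected by the stability analysis", {
  tg <- make_grid(1, 1)
  pars <- model_params(alpha_a = 2, beta_a = 0.7)
  expect_error(jacobian_stability("slow", tg, pars, response_quadratic(),
                                  flux_state(tg, a = 1)), "not an equilibrium")
})

test_that("constructed cycle equilibria match the closed form and are unstable", {
  tg <- triangle_tissue()
  alpha <- 1; beta <- 0.5
  pars <- model_params(alpha_a = alpha, beta_a = beta, mu = 0.4, lambda = 0.8,
                       alpha_p = 1, beta_p = 1)
  cc <- pin_capacity(pars)
  cyc <- orientation(rbind(c(1, 2), c(2, 3), c(3, 1)), 3)
  eq <- construct_equilibrium(cyc, tg, pars, response_quadratic())
  expect_true(eq$ok)
  # rotational symmetry: a = alpha/beta, p = 1/(c a^2) on every edge
  a_star <- alpha / beta
  expect_equal(eq$state$a, rep(a_star, 3), tolerance = 1e-8)
  expect_equal(max(eq$state$p), 1 / (cc * a_star^2), tolerance = 1e-8)
  st <- jacobian_stability("slow", tg, pars, response_quadratic(), eq$state)
  expect_equal(st$classification, "unstable")
})

test_that("analytic slow-variant Jacobians agree with finite differences", {
  tg <- make_grid(2, 2)
  pars <- model_params(alpha_a = c(1, 0.5, 0.7, 0.9), beta_a = 0.6, mu = 0.3,
                       lambda = 1.2, alpha_p = 2, beta_p = 1.5)
  st <- random_state(tg, seed = 8, scale = 1.5)
  Ja <- fluxcanal:::jacobian_slow(st, tg, fluxcanal:::expand_params(pars, tg),
                                  response_quadratic())
  f <- function(y) {
    s <- structure(fluxcanal:::unpack_state(y, tg), class = "flux_state")
    d <- rhs_slow(s, tg, pars, response_quadratic())
    c(d$a, d$p)
  }
  Jn <- fluxcanal:::num_jacobian(f, fluxcanal:::pack_state(st))
  expect_equal(Ja, Jn, tolerance = 1e-5)
})

test_that("sink-tree solutions match the exact subtree-sum formulas", {
  tr <- orientation(rbind(c(1, 2), c(2, 3)), 3)
  sol <- solve_sink_tree(tr, alpha_a = c(1, 1, 1), c = 1, beta_root = 1)
  # fluxes accumulate production toward the root: J = (1, 2), so
  # a = (1/J1, 1/J2, total/beta) = (1, 1/2, 3)
  expect_equal(sol$a, c(1, 0.5, 3))
  expect_equal(sol$subtree_production, c(1, 2, 3))
  expect_equal(sol$p_out[1:2], c(1, 4))
})

test_that("subtree sums agree with an independent reachability computation", {
  for (s in 1:6) {
    n <- withr::with_seed(s, sample(4:12, 1))
    tr <- random_in_tree(n, seed = s)
    alpha <- random_alpha(n, seed = s + 50)
    sol <- solve_sink_tree(tr, alpha, c = 1.7, beta_root = 0.8)
    g <- fluxcanal:::as_igraph_orientation(tr)
    brute <- vapply(seq_len(n), function(i) {
      sum(alpha[as.integer(igraph::subcomponent(g, i, mode = "in"))])
    }, 1)
    expect_equal(sol$subtree_production, brute)
    root <- tree_root(tr)
    expect_equal(sol$a[-root], 1 / (1.7 * brute[-root]))
    expect_equal(sol$a[root], brute[root] / 0.8)
  }
})

test_that("auxin strictly decreases along every path into the sink", {
  for (s in 1:6) {
    n <- withr::with_seed(s + 20, sample(5:12, 1))
    tr <- random_in_tree(n, seed = s + 20)
    alpha <- random_alpha(n, seed = s + 70)
    sol <- solve_sink_tree(tr, alpha, c = 1, beta_root = 1)
    root <- tree_root(tr)
    parent <- rep(NA_integer_, n)
    parent[tr$edges$from] <- tr$edges$to
    for (v in setdiff(seq_len(n), root)) {
      w <- parent[v]
      if (w != root) expect_lt(sol$a[w], sol$a[v])
    }
  }
})

test_that("sink-tree structural errors are reported", {
  not_tree <- orientation(rbind(c(1, 2)), 3)        # node 3 disconnected
  expect_error(solve_sink_tree(not_tree, c(1, 1, 1), 1, 1), "spanning in-tree")
  tr <- orientation(rbind(c(1, 2), c(2, 3)), 3)
  expect_error(solve_sink_tree(tr, c(1, 1, 1), 1, beta_root = 0),
               "no steady state")
  fork <- orientation(rbind(c(2, 1), c(2, 3)), 3)   # out-degree 2 at node 2
  expect_error(solve_sink_tree(fork, c(1, 1, 1), 1, 1), "spanning in-tree")
})

test_that("a sink-tree equilibrium is an exact fixed point of the slow model", {
  tr <- random_in_tree(7, seed = 12)
  alpha <- random_alpha(7, seed = 13)
  root <- tree_root(tr)
  pars <- tree_params(alpha, root, 7)
  sol <- solve_sink_tree(tr, alpha, c = pin_capacity(pars),
                         beta_root = pars$beta_a[root])
  tg <- tissue_of_orientation(tr)
  st <- sink_tree_state(tr, sol, tg)
  d <- rhs_slow(st, tg, pars, response_quadratic())
  expect_lt(max(abs(c(d$a, d$p))), 1e-12)
})

test_that("source chains solve the steady equations with tiny residual", {
  sol <- solve_source_chain(19, alpha = 0.1, alpha0 = 3.1, beta = 0.1, c = 1)
  expect_equal(sol$status, "ok")
  expect_equal(sol$regime, "B")
  tg <- make_line(20)
  p <- numeric(nrow(tg$pairs))
  p[tg$pairs$i < tg$pairs$j] <- sol$cells$p_out[1:19]
  st <- flux_state(tg, a = sol$cells$a, p = p)
  pars <- model_params(alpha_a = c(3.1, rep(0.1, 19)), beta_a = 0.1,
                       mu = 0.01, lambda = 0.01, alpha_p = 1, beta_p = 1)
  d <- rhs_slow(st, tg, pars, response_quadratic())
  expect_lt(max(abs(c(d$a, d$p))), 1e-8)
  # canal body below background and decreasing
  expect_true(all(diff(sol$cells$a[1:19]) < 0))
  expect_lt(max(sol$cells$a[1:19]), 1)
})

test_that("weak sources give with-gradient veins (regime A)", {
  sol <- solve_source_chain(4, alpha = 0.1, alpha0 = 0.9, beta = 0.1, c = 1)
  expect_equal(sol$status, "ok")
  expect_equal(sol$regime, "A")
  expect_true(all(diff(sol$cells$a) > 0))
  expect_gte(sol$cells$a[1], 1)
})

test_that("chain edge cases: lone source, impossible lengths, bad input", {
  sol0 <- solve_source_chain(0, alpha = 0.1, alpha0 = 0.9, beta = 0.1, c = 1)
  expect_equal(sol0$cells$a, 9)
  # a weak source cannot sustain an arbitrarily long with-gradient vein
  long <- solve_source_chain(19, alpha = 0.1, alpha0 = 0.9, beta = 0.1, c = 1)
  expect_equal(long$status, "no_solution")
  expect_equal(long$regime, "other")
  expect_error(solve_source_chain(3, alpha = 0.5, alpha0 = 0.4, beta = 0.1),
               "alpha0 > alpha")
})

test_that("regime classification handles ties and bare profiles", {
  flat <- classify_regime(rep(2, 5), background = 2)
  expect_equal(flat$regime, "A")
  expect_true(flat$degenerate)
  expect_equal(classify_regime(c(2, 2.5, 3), background = 2)$regime, "A")
  expect_equal(classify_regime(c(1.5, 1.2, 1), background = 2)$regime, "B")
  expect_equal(classify_regime(c(1, 3, 2), background = 2)$regime, "other")
  expect_error(classify_regime(c(1, 2, 3)), "background")
})

test_that("the regime map shows the low/high source dichotomy", {
  rm <- regime_map(alpha = 0.1, alpha0 = c(0.05, 0.7, 0.9, 2, 3.1),
                   c = 1, lambda = 0.01, mu = 0.01, beta = 0.1, n = 3)
  lab <- setNames(rm$regime, rm$alpha0)
  expect_equal(unname(lab["0.05"]), "other")   # not a source at all
  expect_equal(unname(lab["0.7"]), "A")
  expect_equal(unname(lab["0.9"]), "A")
  expect_equal(unname(lab["3.1"]), "B")
})

test_that("the regime map is invariant under the steady-state scaling", {
  # (alpha, alpha0, beta) -> s * (alpha, alpha0, beta), c -> c / s leaves
  # the chain steady states (and hence the labels) unchanged
  s <- 3.7
  base <- regime_map(alpha = c(0.1, 0.2), alpha0 = c(0.8, 1.5, 3),
                     c = 1, beta = 0.1, n = 3)
  scaled <- regime_map(alpha = s * c(0.1, 0.2), alpha0 = s * c(0.8, 1.5, 3),
                       c = 1 / s, beta = s * 0.1, n = 3)
  expect_equal(scaled$regime, base$regime)
})

test_that("bounded responses admit steady loops", {
  tg <- make_grid(2, 2)
  pars <- model_params(alpha_a = 1, beta_a = 1, mu = 0.1, lambda = 5)
  rf <- response_hill(rho = 1, theta = 0.5, n = 2)
  pr <- tg$pairs
  cyc <- match(c("1 2", "2 4", "4 3", "3 1"), paste(pr$i, pr$j))
  p0 <- numeric(nrow(pr)); p0[cyc] <- 30
  sim <- simulate_flux("slow", tg, pars, rf, flux_state(tg, a = 1, p = p0),
                       integrator_options(t_max = 5000, rtol = 1e-10,
                                          atol = 1e-12))
  expect_equal(sim$status, "converged")
  orh <- extract_orientation(sim$final_state, tg)
  expect_true(classify_topology(orh)$has_cycle)
})
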