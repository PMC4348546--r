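#' Integrator options
#'
#' @param t_max Final integration time.
#' @param rtol,atol Relative/absolute solver tolerances (passed to the
#'   stiff-capable adaptive solver).
#' @param conv_tol Convergence tolerance on the sup norm of the right-hand
#'   side: the run stops with status `"converged"` once
#'   `||rhs||_inf < conv_tol`.
#' @param blowup_threshold Membrane-PIN level that triggers the finite-time
#'   blow-up detector (ignored in cut-off mode).
#' @param p_max Optional PIN cut-off: membrane PIN is clamped at this value
#'   after every integration step, reproducing the bounded-PIN behaviour of
#'   earlier simulation studies rather than the model's intrinsic dynamics.
#'   Mutually exclusive with blow-up detection.
#' @param osc_window Fraction of the run used as the tail for oscillation
#'   detection.
#' @param osc_tol Relative amplitude above which a stationary tail counts as
#'   oscillating.
#' @param n_chunks Number of integration segments between convergence checks.
#' @param save_per_chunk Trajectory snapshots stored per segment.
#' @param max_steps Internal solver step budget per segment.
#' @return An `integrator_options` list.
#' @export
integrator_options <- function(t_max = 1000, rtol = 1e-8, atol = 1e-10,
                               conv_tol = 1e-8, blowup_threshold = 1e6,
                               p_max = NULL, osc_window = 0.2, osc_tol = 1e-3,
                               n_chunks = 50, save_per_chunk = 8,
                               max_steps = 2e5) {
  stopifnot(t_max > 0, rtol > 0, atol > 0, conv_tol > 0, blowup_threshold > 0,
            osc_window > 0, osc_window <= 1)
  if (!is.null(p_max) && p_max < 0) abort("`p_max` must be nonnegative.")
  structure(list(t_max = t_max, rtol = rtol, atol = atol, conv_tol = conv_tol,
                 blowup_threshold = blowup_threshold, p_max = p_max,
                 osc_window = osc_window, osc_tol = osc_tol,
                 n_chunks = n_chunks, save_per_chunk = save_per_chunk,
                 max_steps = max_steps),
            class = "integrator_options")
}

#' Integrate a model variant
#'
#' Adaptive, stiff-capable integration (lsoda with event-style root
#' termination) of any model variant, with detection of convergence to an
#' equilibrium, finite-time blow-up of membrane PIN, and sustained
#' oscillation. Identical inputs and options give identical results: the
#' integrator holds no hidden randomness.
#'
#' Blow-up is detected numerically, never proven: the run is flagged
#' `"diverged"` when the largest membrane PIN crosses
#' `options$blowup_threshold` while still accelerating upward. The escape
#' time is then estimated as `t_hit + p / (dp/dt)`, the exact remaining time
#' for the locally quadratic PIN growth `dp/dt ~ K p^2` that unbounded
#' responses produce. For bounded responses solutions are global and the
#' detector never fires.
#'
#' @param variant `"slow"`, `"full"` or `"extended"`.
#' @param tissue A [tissue_graph()].
#' @param params A [model_params()].
#' @param response A [response_function()].
#' @param init A [flux_state()] (must carry `P` for `"extended"`).
#' @param options An [integrator_options()].
#' @return A `flux_sim` object: list with `times`, `trajectory` (matrix, one
#'   named column per state variable), `status` (`"converged"`,
#'   `"diverged"`, `"oscillating"`, `"reached_t_max"` or `"failed"`),
#'   `escape_time` (finite iff diverged), `final_state`, `rhs_norm`, and
#'   `diagnostics`.
#' @examples
#' tg <- make_grid(1, 1)
#' pars <- model_params(alpha_a = 1, beta_a = 1)
#' sim <- simulate_flux("slow", tg, pars, response_quadratic(),
#'                      flux_state(tg, a = 0),
#'                      integrator_options(t_max = 50))
#' sim$status
#' @export
simulate_flux <- function(variant = c("slow", "full", "extended"),
                          tissue, params, response, init,
                          options = integrator_options()) {
  variant <- match.arg(variant)
  cyt <- variant == "extended"
  check_state_dims(init, tissue, cytosolic = cyt)
  params <- expand_params(params, tissue)
  y <- pack_state(init)
  names(y) <- state_names(tissue, cytosolic = cyt)
  n_a <- tissue$n_cells
  p_idx <- seq.int(n_a * (1L + cyt) + 1L, length.out = nrow(tissue$pairs))

  d0 <- rhs_variant(variant, init, tissue, params, response)
  if (any(!is.finite(c(d0$a, d0$P, d0$p)))) {
    abort("right-hand side is not finite at the initial state.")
  }
  clamped <- !is.null(options$p_max)
  deriv <- function(t, y, parms) {
    st <- structure(unpack_state(y, tissue, cytosolic = cyt),
                    class = "flux_state")
    d <- rhs_variant(variant, st, tissue, params, response)
    list(c(d$a, d$P, d$p))
  }
  rootfun <- if (!clamped && length(p_idx)) {
    function(t, y, parms) max(y[p_idx]) - options$blowup_threshold
  } else NULL

  bounds <- seq(0, options$t_max, length.out = options$n_chunks + 1)
  traj <- NULL; times <- NULL
  status <- "reached_t_max"; escape_time <- NA_real_
  diag <- list(root_time = NA_real_, chunks_run = 0L, solver_message = NULL)

  for (k in seq_len(options$n_chunks)) {
    tt <- seq(bounds[k], bounds[k + 1], length.out = options$save_per_chunk + 1)
    out <- withCallingHandlers(
      deSolve::ode(y, tt, deriv, NULL,
                   method = if (is.null(rootfun)) "lsoda" else "lsodar",
                   rootfunc = rootfun, rtol = options$rtol, atol = options$atol,
                   maxsteps = options$max_steps),
      warning = function(w) {
        diag$solver_message <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      })
    diag$chunks_run <- k
    troot <- attr(out, "troot")
    keep <- if (k == 1) seq_len(nrow(out)) else seq_len(nrow(out))[-1]
    times <- c(times, out[keep, 1])
    traj <- rbind(traj, out[keep, -1, drop = FALSE])
    y <- out[nrow(out), -1]
    if (clamped && length(p_idx)) {
      y[p_idx] <- pmin(y[p_idx], options$p_max)
    }
    if (!is.null(troot) && length(troot)) {
      # threshold crossed: confirm the upward-accelerating signature
      st <- structure(unpack_state(y, tissue, cytosolic = cyt),
                      class = "flux_state")
      d <- rhs_variant(variant, st, tissue, params, response)
      kmax <- which.max(st$p)
      pdot <- d$p[kmax]
      if (pdot > 0) {
        status <- "diverged"
        escape_time <- troot[1] + st$p[kmax] / pdot
        diag$root_time <- troot[1]
        break
      }
    }
    t_reached <- out[nrow(out), 1]
    if (t_reached < bounds[k + 1] - 1e-9 * options$t_max) {
      status <- "failed"                      # solver gave up without a root
      break
    }
    nrm <- rhs_inf_norm(variant, y, tissue, params, response)
    if (nrm < options$conv_tol) { status <- "converged"; break }
  }

  final <- structure(unpack_state(y, tissue, cytosolic = cyt),
                     class = "flux_state")
  rhs_norm <- rhs_inf_norm(variant, y, tissue, params, response)
  sim <- structure(
    list(times = times, trajectory = traj, status = status,
         escape_time = escape_time, final_state = final, rhs_norm = rhs_norm,
         variant = variant, tissue = tissue, params = params,
         response = response, options = options, diagnostics = diag),
    class = "flux_sim")
  if (status == "reached_t_max" &&
      detect_oscillation(sim, window = options$osc_window,
                         tol = options$osc_tol)) {
    sim$status <- "oscillating"
  }
  sim
}

#' @export
print.flux_sim <- function(x, ...) {
  cat(sprintf("<flux_sim> %s variant, %d cells | status: %s", x$variant,
              x$tissue$n_cells, x$status))
  if (x$status == "diverged") cat(sprintf(" (escape time ~ %g)", x$escape_time))
  cat(sprintf(" | t_end = %g, ||rhs|| = %.3g\n",
              max(x$times), x$rhs_norm))
  invisible(x)
}

#' Convergence and oscillation detectors
#'
#' `detect_convergence()` reports whether the final state of a run is an
#' approximate equilibrium (`||rhs||_inf < tol`). `detect_oscillation()`
#' inspects the tail of a trajectory: the run oscillates when some variable
#' sustains an amplitude above `tol` (relative to its scale) while its
#' windowed mean stays stationary (relative drift below `drift_tol`), i.e.
#' the solution circles an equilibrium instead of approaching or leaving it.
#'
#' @param sim A `flux_sim`, or (for `detect_oscillation()`) a numeric matrix
#'   of trajectory snapshots with rows ordered in time.
#' @param tol Tolerance (rhs norm, or relative amplitude).
#' @param window Tail fraction of the trajectory to inspect.
#' @param drift_tol Maximum relative drift of the windowed mean.
#' @param ... Unused.
#' @export
detect_convergence <- function(sim, tol = NULL) {
  stopifnot(inherits(sim, "flux_sim"))
  tol <- tol %||% sim$options$conv_tol
  sim$rhs_norm < tol
}

#' @rdname detect_convergence
#' @export
detect_oscillation <- function(sim, window = 0.2, tol = 1e-3,
                               drift_tol = 0.1, ...) {
  UseMethod("detect_oscillation")
}

#' @rdname detect_convergence
#' @export
detect_oscillation.flux_sim <- function(sim, window = 0.2, tol = 1e-3,
                                        drift_tol = 0.1, ...) {
  detect_oscillation(sim$trajectory, window = window, tol = tol,
                     drift_tol = drift_tol)
}

#' @rdname detect_convergence
#' @export
detect_oscillation.default <- function(sim, window = 0.2, tol = 1e-3,
                                       drift_tol = 0.1, ...) {
  x <- as.matrix(sim)
  nt <- nrow(x)
  n_tail <- max(4L, ceiling(window * nt))
  if (n_tail > nt) abort("oscillation window longer than the trajectory.")
  tail_x <- x[seq.int(nt - n_tail + 1L, nt), , drop = FALSE]
  half <- seq_len(floor(n_tail / 2))
  m1 <- colMeans(tail_x[half, , drop = FALSE])
  m2 <- colMeans(tail_x[-half, , drop = FALSE])
  amp <- apply(tail_x, 2, function(z) max(z) - min(z))
  scale <- pmax(1e-12, pmax(abs(m1), abs(m2)))
  osc <- amp / scale > tol & abs(m2 - m1) < drift_tol * pmax(amp, 1e-300)
  any(osc)
}

#' Blow-up detector on a trajectory window
#'
#' Standalone form of the detector used inside [simulate_flux()]: given
#' trajectory snapshots of the membrane-PIN variables, it flags finite-time
#' blow-up when the largest value crosses `threshold` while its growth is
#' accelerating (super-linear), and estimates the escape time by
#' extrapolating the locally quadratic growth, `delta = t + p / (dp/dt)`.
#' Trajectories that merely grow linearly never trigger it. The estimate is
#' monotone in `threshold`.
#'
#' @param times Snapshot times.
#' @param p_traj Matrix of membrane-PIN snapshots (rows = times).
#' @param threshold Blow-up threshold.
#' @return The estimated escape time, or `NULL` when no blow-up signature is
#'   present.
#' @export
detect_blowup <- function(times, p_traj, threshold = 1e6) {
  p_traj <- as.matrix(p_traj)
  stopifnot(length(times) == nrow(p_traj))
  pmaxs <- apply(p_traj, 1, max)
  hit <- which(pmaxs >= threshold)
  if (!length(hit)) return(NULL)
  k <- hit[1]
  if (k < 3) return(NULL)                     # need history to judge growth
  dt1 <- times[k] - times[k - 1]
  dt2 <- times[k - 1] - times[k - 2]
  g1 <- (pmaxs[k] - pmaxs[k - 1]) / dt1
  g2 <- (pmaxs[k - 1] - pmaxs[k - 2]) / dt2
  if (!(g1 > 0 && g1 > 1.05 * g2)) return(NULL)  # not accelerating: no flag
  times[k] + pmaxs[k] / g1
}

#' Integrate with a PIN cut-off
#'
#' Clamps every membrane PIN at `p_max` after each integration segment, the
#' device earlier simulation studies used to keep PIN bounded under
#' unbounded responses. A clamped run never reports `"diverged"`; it
#' reproduces that literature's behaviour, not the model's intrinsic
#' dynamics (which can genuinely escape in finite time).
#'
#' @inheritParams simulate_flux
#' @param p_max The cut-off (>= 0). `p_max = 0` switches active transport off
#'   entirely.
#' @return A `flux_sim`; see [simulate_flux()].
#' @export
run_with_cutoff <- function(variant, tissue, params, response, init,
                            options = integrator_options(), p_max) {
  stopifnot(p_max >= 0)
  options$p_max <- p_max
  options$n_chunks <- max(options$n_chunks, 100L)  # fine-grained projection
  init$p <- pmin(init$p, p_max)
  simulate_flux(variant, tissue, params, response, init, options)
}

#' Slow-PIN reduction check
#'
#' Runs the extended model under the scaling `alpha_p/epsilon`,
#' `beta_p/epsilon`, `gamma_D * epsilon` for each requested `epsilon`, from
#' the initial condition matched to a converging slow-variant run (cytosolic
#' PIN started at its quasi-steady value `alpha_p / beta_p`), and reports the
#' sup-norm deviation of `(a, p)` from the slow trajectory over the common
#' time grid. As `epsilon` shrinks the extended dynamics collapse onto the
#' slow variant, so deviations should shrink too.
#'
#' @inheritParams simulate_flux
#' @param epsilons Decreasing vector of scaling parameters.
#' @param t_max Comparison horizon.
#' @param n_times Number of comparison time points.
#' @return A tibble with columns `epsilon` and `sup_dev`.
#' @export
compare_slow_fast <- function(tissue, params, response, init,
                              epsilons = c(0.1, 0.01, 0.001), t_max = 100,
                              n_times = 101,
                              options = integrator_options(t_max = t_max)) {
  options$t_max <- t_max
  slow <- simulate_flux("slow", tissue, params, response, init, options)
  if (slow$status != "converged") {
    abort(sprintf(
      "the slow-variant run did not converge (status '%s', ||rhs|| = %.3g); %s",
      slow$status, slow$rhs_norm,
      "the reduction comparison needs a convergent reference."))
  }
  grid <- seq(0, t_max, length.out = n_times)
  cyt_names <- state_names(tissue, cytosolic = FALSE)
  deriv_for <- function(variant, pars) {
    function(t, y, parms) {
      st <- structure(unpack_state(y, tissue, cytosolic = variant == "extended"),
                      class = "flux_state")
      d <- rhs_variant(variant, st, tissue, pars, response)
      list(c(d$a, d$P, d$p))
    }
  }
  slow_tr <- deSolve::ode(pack_state(init), grid, deriv_for("slow", params),
                          NULL, method = "lsoda", rtol = options$rtol,
                          atol = options$atol, maxsteps = options$max_steps)
  purrr::map_dfr(epsilons, function(eps) {
    pars <- params
    pars$alpha_p <- params$alpha_p / eps
    pars$beta_p <- params$beta_p / eps
    pars$gamma_D <- params$gamma_D * eps
    ext_init <- flux_state(tissue, a = init$a, p = init$p,
                           P = pars$alpha_p / pars$beta_p)
    ext_tr <- deSolve::ode(pack_state(ext_init), grid,
                           deriv_for("extended", pars), NULL,
                           method = "lsoda", rtol = options$rtol,
                           atol = options$atol, maxsteps = options$max_steps)
    n <- tissue$n_cells
    keep_ext <- c(seq_len(n), 2 * n + seq_len(nrow(tissue$pairs)))
    dev <- max(abs(ext_tr[, 1 + keep_ext] - slow_tr[, -1]))
    tibble(epsilon = eps, sup_dev = dev)
  })
}
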