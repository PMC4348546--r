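#' Membrane fluxes
#'
#' The net auxin flux through the membrane face from cell `i` to cell `j` is
#' the sum of a passive Fickian part, `gamma_D * (a_i - a_j)`, and an active
#' PIN-driven part, `gamma_A * (a_i * p_ij - a_j * p_ji)`. Both parts are
#' antisymmetric: `J_(i->j) = -J_(j->i)` exactly.
#'
#' @param a_i,a_j Auxin concentrations in the two cells.
#' @param p_ij,p_ji Membrane PIN on the two faces of the shared membrane.
#' @param gamma_D,gamma_A Transport rate constants.
#' @return Flux in mol m^-2 s^-1 (working units).
#' @export
diffusive_flux <- function(a_i, a_j, gamma_D) gamma_D * (a_i - a_j)

#' @rdname diffusive_flux
#' @export
active_flux <- function(a_i, a_j, p_ij, p_ji, gamma_A) {
  gamma_A * (a_i * p_ij - a_j * p_ji)
}

# all ordered-pair fluxes at once; p aligned with tissue$pairs
pair_fluxes <- function(a, p, tissue, gamma_D, gamma_A) {
  pr <- tissue$pairs
  gamma_D * (a[pr$i] - a[pr$j]) + gamma_A * (a[pr$i] * p - a[pr$j] * p[pr$rev])
}

# per-cell sum of S_ij * x over faces (i -> j), divided by V_i
surface_sum <- function(x, tissue) {
  pr <- tissue$pairs
  s <- rep(0, tissue$n_cells)
  if (nrow(pr)) {
    area <- tissue$edges$area[pr$edge]
    agg <- rowsum(area * x, pr$i)
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  s / tissue$cells$volume
}

#' Right-hand sides of the model variants
#'
#' The three variants share the transport law but differ in how membrane PIN
#' is replenished:
#'
#' * `rhs_full()`: the original model. Auxin follows
#'   `da_i/dt = alpha_ai - beta_ai a_i - (1/V_i) sum_j S_ij J_(i->j)` and each
#'   membrane face follows `dp_ij/dt = h(J_(i->j)) + rho0 - mu p_ij`.
#' * `rhs_extended()`: adds cytosolic PIN cycling,
#'   `dP_i/dt = alpha_p - beta_p P_i + (1/V_i) sum_j S_ij (mu p_ij - lambda P_i h(J_(i->j)))`
#'   and `dp_ij/dt = lambda P_i h(J_(i->j)) - mu p_ij`. With
#'   `alpha_p = beta_p = 0` the per-cell total [total_cell_pin()] is
#'   conserved identically.
#' * `rhs_slow()`: the simplified slow-PIN variant on a regular tissue with
#'   negligible diffusion, `da_i/dt = alpha_ai - beta_ai a_i +
#'   sum_k (a_k p_ki - a_i p_ik)`, `dp_ij/dt = lambda (alpha_p/beta_p)
#'   Phi(J_(i->j)) - mu p_ij` with `J_(i->j) = a_i p_ij - a_j p_ji`. Basal
#'   insertion (`rho0`) is absent from this variant: the steady-state
#'   complementarity (`p_ij* = 0` or `p_ji* = 0` on every membrane), which
#'   underpins orientation extraction, requires it.
#'
#' @param state A [flux_state()] (with `P` for the extended variant).
#' @param tissue A [tissue_graph()].
#' @param params A [model_params()].
#' @param response A [response_function()].
#' @return A list with components `a`, `P` (extended only) and `p` holding
#'   the time derivatives, aligned with the state.
#' @examples
#' tg <- make_line(2)
#' pars <- model_params(alpha_a = 1, beta_a = 1)
#' st <- flux_state(tg, a = 1, p = 0)
#' rhs_slow(st, tg, pars, response_quadratic())
#' @export
rhs_full <- function(state, tissue, params, response) {
  check_state_dims(state, tissue, cytosolic = FALSE)
  params <- expand_params(params, tissue)
  J <- pair_fluxes(state$a, state$p, tissue, params$gamma_D, params$gamma_A)
  da <- params$alpha_a - params$beta_a * state$a - surface_sum(J, tissue)
  dp <- rf_eval(response, J) + params$rho0 - params$mu * state$p
  list(a = da, P = NULL, p = dp)
}

#' @rdname rhs_full
#' @export
rhs_extended <- function(state, tissue, params, response) {
  check_state_dims(state, tissue, cytosolic = TRUE)
  params <- expand_params(params, tissue)
  J <- pair_fluxes(state$a, state$p, tissue, params$gamma_D, params$gamma_A)
  h <- rf_eval(response, J)
  Pi <- state$P[tissue$pairs$i]
  ins <- params$lambda * Pi * h           # membrane insertion per face
  da <- params$alpha_a - params$beta_a * state$a - surface_sum(J, tissue)
  dP <- params$alpha_p - params$beta_p * state$P +
    surface_sum(params$mu * state$p - ins, tissue)
  dp <- ins - params$mu * state$p
  list(a = da, P = dP, p = dp)
}

#' @rdname rhs_full
#' @export
rhs_slow <- function(state, tissue, params, response) {
  check_state_dims(state, tissue, cytosolic = FALSE)
  if (!tissue$regular) {
    abort("the slow-PIN variant requires a regular tissue.")
  }
  params <- expand_params(params, tissue)
  pr <- tissue$pairs
  J <- state$a[pr$i] * state$p - state$a[pr$j] * state$p[pr$rev]
  out_J <- rep(0, tissue$n_cells)
  if (nrow(pr)) {
    agg <- rowsum(J, pr$i)
    out_J[as.integer(rownames(agg))] <- agg[, 1]
  }
  da <- params$alpha_a - params$beta_a * state$a - out_J
  Pbar <- if (params$beta_p > 0) params$alpha_p / params$beta_p else
    abort("the slow-PIN variant requires `beta_p > 0`.")
  dp <- params$lambda * Pbar * rf_eval(response, J) - params$mu * state$p
  list(a = da, P = NULL, p = dp)
}

check_state_dims <- function(state, tissue, cytosolic) {
  stopifnot(inherits(state, "flux_state"), inherits(tissue, "tissue_graph"))
  if (length(state$a) != tissue$n_cells ||
      length(state$p) != nrow(tissue$pairs)) {
    abort("state dimensions do not match the tissue.")
  }
  if (cytosolic && is.null(state$P)) {
    abort("the extended variant needs a cytosolic PIN component `P`.")
  }
  invisible(TRUE)
}

#' Total PIN of a cell
#'
#' The cytosolic-plus-membrane PIN of cell `i`,
#' `P_i + (1/V_i) sum_j S_ij p_ij`. Under the extended variant with
#' `alpha_p = beta_p = 0` this quantity is a conserved first integral of the
#' dynamics, cell by cell.
#'
#' @param state A [flux_state()] with cytosolic PIN.
#' @param tissue A [tissue_graph()].
#' @param cells Cells to report (default all).
#' @return A numeric vector of totals.
#' @export
total_cell_pin <- function(state, tissue, cells = NULL) {
  check_state_dims(state, tissue, cytosolic = TRUE)
  tot <- state$P + surface_sum(state$p, tissue)
  if (is.null(cells)) tot else tot[cells]
}

# generic dispatch used by the integrator
rhs_variant <- function(variant, state, tissue, params, response) {
  switch(variant,
         full = rhs_full(state, tissue, params, response),
         extended = rhs_extended(state, tissue, params, response),
         slow = rhs_slow(state, tissue, params, response),
         abort(sprintf("unknown model variant '%s'.", variant)))
}

# flat-vector rhs norm, used for convergence checks
rhs_inf_norm <- function(variant, y, tissue, params, response) {
  cyt <- variant == "extended"
  st <- unpack_state(y, tissue, cytosolic = cyt)
  st <- structure(st, class = "flux_state")
  d <- rhs_variant(variant, st, tissue, params, response)
  max(abs(c(d$a, d$P, d$p)))
}
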