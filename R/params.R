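#' Model rate parameters
#'
#' Collects the rate constants of all model variants. Auxin synthesis
#' `alpha_a` (mol m^-3 s^-1) and degradation `beta_a` (s^-1) may be per-cell
#' vectors (recycled against the tissue at evaluation time); the remaining
#' rates are scalars. Units are taken as consistent, user-supplied working
#' units throughout; there is no unit-conversion layer.
#'
#' @param alpha_a Auxin synthesis rate(s), per cell.
#' @param beta_a Auxin degradation rate(s), per cell.
#' @param gamma_D Passive (Fickian) membrane permeability (m s^-1).
#' @param gamma_A Active-transport efficiency of the PIN pumps
#'   (m^3 mol^-1 s^-1).
#' @param rho0 Basal PIN insertion rate into the membrane (mol m^-2 s^-1);
#'   only the full model uses it.
#' @param mu Basal PIN removal rate from the membrane (s^-1).
#' @param lambda PIN insertion rate constant coupling cytosolic PIN to the
#'   flux response.
#' @param alpha_p,beta_p Cytosolic PIN production and degradation rates.
#' @return A `model_params` object.
#' @details The composite constant `c = lambda * alpha_p / (mu * beta_p)`
#'   ([pin_capacity()]) controls the steady-state membrane PIN
#'   `p* = c * Phi(J*)` of the slow-PIN variant and is all that the
#'   steady-state structure depends on; `lambda` and `mu` separately set the
#'   PIN time scale and hence stability and transients.
#' @examples
#' pars <- model_params(alpha_a = 0.1, beta_a = 0.1, lambda = 0.01, mu = 0.01)
#' pin_capacity(pars)
#' @export
model_params <- function(alpha_a, beta_a, gamma_D = 0, gamma_A = 1, rho0 = 0,
                         mu = 1, lambda = 1, alpha_p = 1, beta_p = 1) {
  sc <- c(gamma_D = gamma_D, gamma_A = gamma_A, rho0 = rho0, mu = mu,
          lambda = lambda, alpha_p = alpha_p, beta_p = beta_p)
  if (any(!is.finite(sc)) || any(sc < 0)) {
    abort("all rate constants must be nonnegative and finite.")
  }
  if (any(alpha_a < 0) || any(beta_a < 0)) {
    abort("`alpha_a` and `beta_a` must be nonnegative.")
  }
  structure(
    list(alpha_a = as.double(alpha_a), beta_a = as.double(beta_a),
         gamma_D = gamma_D, gamma_A = gamma_A, rho0 = rho0, mu = mu,
         lambda = lambda, alpha_p = alpha_p, beta_p = beta_p),
    class = "model_params"
  )
}

#' @rdname model_params
#' @param params A `model_params` object.
#' @export
pin_capacity <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$mu <= 0 || params$beta_p <= 0) {
    abort("`mu` and `beta_p` must be positive for the PIN capacity c to be finite.")
  }
  params$lambda * params$alpha_p / (params$mu * params$beta_p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  alpha_a: %s\n", paste(signif(unique(x$alpha_a), 4), collapse = ", ")))
  cat(sprintf("  beta_a:  %s\n", paste(signif(unique(x$beta_a), 4), collapse = ", ")))
  cat(sprintf("  gamma_D = %g, gamma_A = %g, rho0 = %g\n", x$gamma_D, x$gamma_A, x$rho0))
  cat(sprintf("  mu = %g, lambda = %g, alpha_p = %g, beta_p = %g\n",
              x$mu, x$lambda, x$alpha_p, x$beta_p))
  invisible(x)
}

# recycle per-cell rates against a tissue
expand_params <- function(params, tissue) {
  params$alpha_a <- rep_len(params$alpha_a, tissue$n_cells)
  params$beta_a <- rep_len(params$beta_a, tissue$n_cells)
  params
}

#' Normalize parameters on a regular tissue
#'
#' On a regular tissue with surface-to-volume ratio `W`, the model collapses
#' to normalized rates `D = gamma_D * W`, `T = gamma_A * W` and the
#' normalized response `Phi(x) = h(x / W)`. Optionally applies the slow-PIN
#' scaling `alpha_p -> alpha_p / epsilon`, `beta_p -> beta_p / epsilon`,
#' `D -> D * epsilon`, under which the PIN capacity `c` is invariant and the
#' dynamics approach the simplified slow variant as `epsilon -> 0`.
#'
#' @param tissue A regular [tissue_graph()].
#' @param params A [model_params()].
#' @param response The response function `h` (a [response_function()]).
#' @param epsilon Optional scaling parameter (> 0).
#' @return A list with `D`, `T`, `Phi` (a `response_fn` evaluating
#'   `h(x / W)`), the scaled `params`, and `W`.
#' @export
normalize_params <- function(tissue, params, response, epsilon = NULL) {
  stopifnot(inherits(tissue, "tissue_graph"), inherits(params, "model_params"))
  if (!tissue$regular) abort("parameter normalization requires a regular tissue.")
  W <- tissue$W
  D <- params$gamma_D * W
  Tn <- params$gamma_A * W
  Phi <- if (W == 1) response else {
    response_function("custom",
                      fun = function(x) rf_eval(response, x / W),
                      bounded = rf_bounded(response))
  }
  scaled <- params
  if (!is.null(epsilon)) {
    if (epsilon <= 0) abort("`epsilon` must be positive.")
    scaled$alpha_p <- params$alpha_p / epsilon
    scaled$beta_p <- params$beta_p / epsilon
    D <- D * epsilon
    scaled$gamma_D <- D / W
  }
  list(D = D, T = Tn, Phi = Phi, params = scaled, W = W)
}

#' Predicate for the source-strength condition
#'
#' The source-driven analysis assumes the source production rate `alpha0`
#' dominates the background production `alpha`. The middle term of the
#' printed condition is typographically ambiguous between `2 * beta * c` and
#' `2 * beta / c`; both readings are exposed here rather than hard-coded into
#' any solver. (For a length-1 vein a real steady flux out of the source
#' additionally requires `alpha0 >= 2 * sqrt(beta / c)`.)
#'
#' @param alpha,alpha0,beta Background production, source production and
#'   uniform degradation rates.
#' @param c PIN capacity `lambda * alpha_p / (mu * beta_p)`.
#' @param reading `"times"` for `alpha0 >= 2 beta c`, `"divide"` for
#'   `alpha0 >= 2 beta / c`.
#' @return Logical: does `(alpha, alpha0)` satisfy the chosen reading and
#'   `alpha0 > alpha`?
#' @export
source_condition <- function(alpha, alpha0, beta, c = 1,
                             reading = c("times", "divide")) {
  reading <- match.arg(reading)
  mid <- if (reading == "times") 2 * beta * c else 2 * beta / c
  alpha0 >= mid & mid > alpha & alpha0 > alpha
}
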