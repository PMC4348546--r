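#' Flux-response functions
#'
#' The response function `h` maps the net auxin flux through a membrane to
#' the PIN insertion rate on that membrane, and is the source of the
#' canalization feedback. All kinds are *rectified*: `h(J) = 0` for `J <= 0`
#' (no insertion on membranes with net influx), nondecreasing and nonnegative
#' for `J > 0`.
#'
#' Available kinds, for `x > 0`:
#' * `linear`: `kappa * x / J_ref`
#' * `quadratic`: `kappa * (x / J_ref)^2` (the canonical unbounded choice)
#' * `hill`: `rho * x^n / (theta^n + x^n)` (bounded, saturating at `rho`)
#' * `power`: `rho * x^n` (unbounded for `n >= 1`)
#' * `custom`: a user function of the positive part; `bounded` must be given
#'
#' Whether `h` is bounded decides the global behaviour of the dynamics:
#' bounded responses yield globally defined solutions, unbounded ones admit
#' finite-time blow-up of membrane PIN.
#'
#' @param kind One of `"linear"`, `"quadratic"`, `"hill"`, `"power"`,
#'   `"custom"`.
#' @param kappa,J_ref Scale and reference flux of the linear/quadratic kinds.
#' @param rho,theta,n Shape parameters of the hill/power kinds.
#' @param fun For `kind = "custom"`: a vectorized function evaluated on the
#'   positive part of the flux.
#' @param bounded For `kind = "custom"`: is `sup h` finite?
#' @return A `response_fn` object.
#' @examples
#' q <- response_quadratic()
#' rf_eval(q, c(-3, 2))   # 0, 4
#' rf_bounded(response_hill(n = 2))
#' @export
response_function <- function(kind = c("linear", "quadratic", "hill", "power",
                                       "custom"),
                              kappa = 1, J_ref = 1, rho = 1, theta = 1, n = 2,
                              fun = NULL, bounded = NULL) {
  kind <- match.arg(kind)
  pars <- c(kappa = kappa, J_ref = J_ref, rho = rho, theta = theta, n = n)
  if (any(!is.finite(pars)) || any(pars < 0)) {
    abort("response-function shape parameters must be nonnegative and finite.")
  }
  if (kind %in% c("linear", "quadratic") && J_ref <= 0) {
    abort("`J_ref` must be positive.")
  }
  if (kind == "custom") {
    if (!is.function(fun)) abort("`fun` is required for a custom response.")
    if (is.null(bounded)) abort("`bounded` is required for a custom response.")
  } else {
    bounded <- kind == "hill"
  }
  structure(
    list(kind = kind, kappa = kappa, J_ref = J_ref, rho = rho, theta = theta,
         n = n, fun = fun, bounded = isTRUE(bounded)),
    class = "response_fn"
  )
}

#' @rdname response_function
#' @export
response_linear <- function(kappa = 1, J_ref = 1) {
  response_function("linear", kappa = kappa, J_ref = J_ref)
}

#' @rdname response_function
#' @export
response_quadratic <- function(kappa = 1, J_ref = 1) {
  response_function("quadratic", kappa = kappa, J_ref = J_ref)
}

#' @rdname response_function
#' @export
response_hill <- function(rho = 1, theta = 1, n = 2) {
  response_function("hill", rho = rho, theta = theta, n = n)
}

#' @rdname response_function
#' @export
response_power <- function(rho = 1, n = 2) {
  response_function("power", rho = rho, n = n)
}

#' Evaluate a response function
#'
#' @param rf A [response_function()].
#' @param x Fluxes (any numeric vector).
#' @return `rf_eval()`: the insertion rates, 0 wherever `x <= 0`.
#' @export
rf_eval <- function(rf, x) {
  stopifnot(inherits(rf, "response_fn"))
  pos <- x > 0
  out <- numeric(length(x))
  if (!any(pos)) return(out)
  xp <- x[pos]
  out[pos] <- switch(
    rf$kind,
    linear = rf$kappa * xp / rf$J_ref,
    quadratic = rf$kappa * (xp / rf$J_ref)^2,
    hill = rf$rho * xp^rf$n / (rf$theta^rf$n + xp^rf$n),
    power = rf$rho * xp^rf$n,
    custom = rf$fun(xp)
  )
  out
}

#' @rdname rf_eval
#' @return `rf_deriv()`: the one-sided rectified derivative `h'(x)`, taken as
#'   0 for `x <= 0`. For the quadratic kind the rectified map is C1 with
#'   `h'(0) = 0`, so Jacobians of the dynamics are well defined.
#' @export
rf_deriv <- function(rf, x) {
  stopifnot(inherits(rf, "response_fn"))
  pos <- x > 0
  out <- numeric(length(x))
  if (!any(pos)) return(out)
  xp <- x[pos]
  out[pos] <- switch(
    rf$kind,
    linear = rf$kappa / rf$J_ref + 0 * xp,
    quadratic = 2 * rf$kappa * xp / rf$J_ref^2,
    hill = rf$rho * rf$n * rf$theta^rf$n * xp^(rf$n - 1) /
      (rf$theta^rf$n + xp^rf$n)^2,
    power = rf$rho * rf$n * xp^(rf$n - 1),
    custom = {
      h <- 1e-6 * pmax(1, abs(xp))
      (rf$fun(xp + h) - rf$fun(pmax(xp - h, 0))) / (h + pmin(xp, h))
    }
  )
  out
}

#' @rdname rf_eval
#' @return `rf_bounded()`: `TRUE` iff `sup h` over positive fluxes is finite.
#' @export
rf_bounded <- function(rf) {
  stopifnot(inherits(rf, "response_fn"))
  rf$bounded
}

#' @export
print.response_fn <- function(x, ...) {
  par_str <- switch(
    x$kind,
    linear = ,
    quadratic = sprintf("kappa = %g, J_ref = %g", x$kappa, x$J_ref),
    hill = sprintf("rho = %g, theta = %g, n = %g", x$rho, x$theta, x$n),
    power = sprintf("rho = %g, n = %g", x$rho, x$n),
    custom = "user-supplied"
  )
  cat(sprintf("<response_fn> %s (%s), %s\n", x$kind,
              if (x$bounded) "bounded" else "unbounded", par_str))
  invisible(x)
}
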