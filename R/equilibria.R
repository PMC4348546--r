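# central-difference Jacobian; step scaled per coordinate
num_jacobian <- function(f, x, h = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (k in seq_len(n)) {
    dx <- h * max(1, abs(x[k]))
    xp <- x; xp[k] <- x[k] + dx
    xm <- x; xm[k] <- x[k] - dx
    J[, k] <- (f(xp) - f(xm)) / (2 * dx)
  }
  J
}

# damped (backtracking) Newton for square systems; returns list(x, ok, res)
damped_newton <- function(f, x0, tol = 1e-12, max_iter = 60) {
  x <- x0
  r <- f(x)
  for (it in seq_len(max_iter)) {
    nr <- max(abs(r))
    if (!is.finite(nr)) return(list(x = x, ok = FALSE, res = nr, iter = it))
    if (nr < tol) return(list(x = x, ok = TRUE, res = nr, iter = it))
    J <- num_jacobian(f, x)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) return(list(x = x, ok = FALSE, res = nr, iter = it))
    lam <- 1
    repeat {
      xn <- x + lam * step
      rn <- f(xn)
      if (all(is.finite(rn)) && max(abs(rn)) < nr) break
      lam <- lam / 2
      if (lam < 1e-10) return(list(x = x, ok = FALSE, res = nr, iter = it))
    }
    x <- xn; r <- rn
  }
  list(x = x, ok = max(abs(r)) < tol, res = max(abs(r)), iter = max_iter)
}

# analytic Jacobian of the slow-PIN variant at a state (uses the rectified
# one-sided response derivative, 0 at nonpositive fluxes)
jacobian_slow <- function(state, tissue, params, response) {
  params <- expand_params(params, tissue)
  pr <- tissue$pairs
  n <- tissue$n_cells
  np <- nrow(pr)
  a <- state$a; p <- state$p
  J <- a[pr$i] * p - a[pr$j] * p[pr$rev]
  lamP <- params$lambda * params$alpha_p / params$beta_p
  dPhi <- rf_deriv(response, J)
  M <- matrix(0, n + np, n + np)
  # auxin rows
  for (k in seq_len(np)) {
    i <- pr$i[k]; j <- pr$j[k]
    # d(da_i)/d(.) from the outgoing term -J_k = -(a_i p_k - a_j p_rev)
    M[i, i] <- M[i, i] - p[k]
    M[i, j] <- M[i, j] + p[pr$rev[k]]
    M[i, n + k] <- M[i, n + k] - a[i]
    M[i, n + pr$rev[k]] <- M[i, n + pr$rev[k]] + a[j]
  }
  diag(M)[seq_len(n)] <- diag(M)[seq_len(n)] - params$beta_a
  # membrane rows
  for (k in seq_len(np)) {
    i <- pr$i[k]; j <- pr$j[k]
    row <- n + k
    g <- lamP * dPhi[k]
    M[row, i] <- M[row, i] + g * p[k]
    M[row, j] <- M[row, j] - g * p[pr$rev[k]]
    M[row, n + k] <- M[row, n + k] + g * a[i] - params$mu
    M[row, n + pr$rev[k]] <- M[row, n + pr$rev[k]] - g * a[j]
  }
  M
}

#' Linear stability of an equilibrium
#'
#' Forms the Jacobian of the chosen model variant at an equilibrium
#' (analytically for the slow-PIN variant, whose rectified quadratic
#' response is C1 with derivative 0 at nonpositive flux; by central finite
#' differences otherwise) and classifies the equilibrium by the spectrum:
#' `"stable"` when all eigenvalues have real part below `-tol_eig`,
#' `"unstable"` when some real part exceeds `+tol_eig`, `"marginal"`
#' otherwise.
#'
#' @inheritParams simulate_flux
#' @param equilibrium A [flux_state()] with `||rhs||_inf < tol_eq`.
#' @param tol_eq Equilibrium residual tolerance (precondition check).
#' @param tol_eig Spectral tolerance separating the three classes.
#' @return A `stability_analysis`: list with `classification`,
#'   `eigenvalues`, `max_re` and the Jacobian.
#' @export
jacobian_stability <- function(variant = c("slow", "full", "extended"),
                               tissue, params, response, equilibrium,
                               tol_eq = 1e-6, tol_eig = 1e-8) {
  variant <- match.arg(variant)
  params <- expand_params(params, tissue)
  nrm <- rhs_inf_norm(variant, pack_state(equilibrium), tissue, params, response)
  if (nrm >= tol_eq) {
    abort(sprintf("not an equilibrium: ||rhs||_inf = %.3g >= tol_eq = %.3g.",
                  nrm, tol_eq))
  }
  Jm <- if (variant == "slow") {
    jacobian_slow(equilibrium, tissue, params, response)
  } else {
    cyt <- variant == "extended"
    f <- function(y) {
      st <- structure(unpack_state(y, tissue, cytosolic = cyt),
                      class = "flux_state")
      d <- rhs_variant(variant, st, tissue, params, response)
      c(d$a, d$P, d$p)
    }
    num_jacobian(f, pack_state(equilibrium))
  }
  ev <- eigen(Jm, only.values = TRUE)$values
  max_re <- max(Re(ev))
  cls <- if (max_re < -tol_eig) "stable" else if (max_re > tol_eig) "unstable" else "marginal"
  structure(list(classification = cls, eigenvalues = ev, max_re = max_re,
                 jacobian = Jm),
            class = "stability_analysis")
}

#' @export
print.stability_analysis <- function(x, ...) {
  cat(sprintf("<stability_analysis> %s (max Re eigenvalue = %.4g, %d eigenvalues)\n",
              x$classification, x$max_re, length(x$eigenvalues)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.stability_analysis <- function(x, ...) {
  tibble(eigenvalue = seq_along(x$eigenvalues),
         re = Re(x$eigenvalues), im = Im(x$eigenvalues))
}

#' @exportS3Method generics::glance
glance.stability_analysis <- function(x, ...) {
  tibble(classification = x$classification, max_re = x$max_re,
         n_eigenvalues = length(x$eigenvalues))
}

#' Construct a slow-model equilibrium on a prescribed orientation
#'
#' Solves the slow-PIN steady-state equations with membrane PIN restricted
#' to the support of a prescribed orientation (all other faces exactly
#' zero), by damped Newton root-finding with seeded multistart. This is how
#' equilibria on chosen topologies - sinkless cycles, out-degree-2 stars,
#' in-trees - are produced for spectral analysis.
#'
#' @param orient A [orientation()] giving the directed support.
#' @param tissue The underlying [tissue_graph()] (must contain each oriented
#'   edge as an undirected edge).
#' @param params,response Model parameters and response function.
#' @param n_starts Number of random multistart seeds after the deterministic
#'   seed fails.
#' @param seed RNG seed for the multistart draws.
#' @param tol Residual tolerance.
#' @return A list with `state` (a [flux_state()]), `ok` (root-finder
#'   converged with positive PIN and positive oriented fluxes), and
#'   `residual`.
#' @export
construct_equilibrium <- function(orient, tissue, params, response,
                                  n_starts = 10, seed = 1L, tol = 1e-12) {
  stopifnot(inherits(orient, "pin_orientation"))
  params <- expand_params(params, tissue)
  n <- tissue$n_cells
  ne <- nrow(orient$edges)
  pr <- tissue$pairs
  # map oriented edges onto ordered-pair slots
  key <- paste(pr$i, pr$j)
  slot <- match(paste(orient$edges$from, orient$edges$to), key)
  if (anyNA(slot)) abort("orientation contains an edge absent from the tissue.")
  lamP <- params$lambda * params$alpha_p / params$beta_p
  resid <- function(x) {
    a <- x[seq_len(n)]
    pe <- x[n + seq_len(ne)]
    p <- rep(0, nrow(pr)); p[slot] <- pe
    J <- a[pr$i] * p - a[pr$j] * p[pr$rev]
    agg <- rowsum(J, pr$i)
    outJ <- rep(0, n); outJ[as.integer(rownames(agg))] <- agg[, 1]
    c(params$alpha_a - params$beta_a * a - outJ,
      lamP * rf_eval(response, J[slot]) - params$mu * pe)
  }
  a0 <- ifelse(params$beta_a > 0, params$alpha_a / pmax(params$beta_a, 1e-12), 1)
  # flux-balance heuristic seed: each oriented edge carries roughly its
  # source cell's production split over its out-edges; cells with out-flow
  # sit near a = J / p = 1 / (lamP/mu * Phi(J) / J) for the quadratic case
  out_deg <- tabulate(orient$edges$from, nbins = n)
  J_guess <- pmax(params$alpha_a[orient$edges$from] /
                    pmax(out_deg[orient$edges$from], 1), 1e-3)
  p_guess <- pmax(lamP / params$mu * rf_eval(response, J_guess), 1e-3)
  a_guess <- a0
  has_out <- out_deg > 0
  a_guess[has_out] <- J_guess[match(which(has_out), orient$edges$from)] /
    p_guess[match(which(has_out), orient$edges$from)]
  # nonzero membrane PIN below this level means the root-finder collapsed
  # onto the all-isolated equilibrium rather than one on the prescribed support
  p_floor <- 1e-6
  starts <- c(list(c(a_guess, p_guess), c(a0, rep(1, ne))),
              with_local_seed(seed, purrr::map(seq_len(n_starts), function(s) {
                c(a0 * runif(n, 0.2, 3), runif(ne, 0.05, 5))
              })))
  best <- NULL
  for (x0 in starts) {
    sol <- damped_newton(resid, x0, tol = tol)
    valid <- sol$ok && all(sol$x[n + seq_len(ne)] > p_floor) &&
      all(sol$x[seq_len(n)] > 0)
    if (valid) { best <- sol; break }
    if (is.null(best) || sol$res < best$res) best <- sol
  }
  a <- best$x[seq_len(n)]
  pe <- best$x[n + seq_len(ne)]
  p <- rep(0, nrow(pr)); p[slot] <- pe
  ok <- best$ok && all(pe > p_floor) && all(a > 0)
  st <- flux_state(tissue, a = pmax(a, 0), p = pmax(p, 0))
  list(state = st, ok = ok, residual = best$res)
}
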