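#' Source-driven vein (linear chain) steady state
#'
#' In the source-driven setting every cell degrades auxin at rate `beta`
#' and produces it at rate `alpha`, except a single source `i0` producing at
#' `alpha0 > alpha`. The steady orientation emanating from the source is a
#' linear chain `i0 -> i1 -> ... -> in`; off-chain cells are isolated at the
#' background level `alpha / beta`. On the chain (quadratic response,
#' PIN capacity `c`) the steady state satisfies, per edge `k`,
#' `p_k = c * J_k^2` with `J_k = a_k * p_k` (the reverse face is zero), and
#' per cell the production/degradation/flux balance. Eliminating `p_k` gives
#' `a_k = 1 / (c * J_k)` and a quadratic recursion for the edge fluxes:
#' `J_0^2 - alpha0 * J_0 + beta/c = 0`,
#' `J_k^2 - (alpha + J_(k-1)) * J_k + beta/c = 0`, and
#' `a_n = (alpha + J_(n-1)) / beta` at the chain tip. The upper root of each
#' quadratic is the branch simulations select; it is used (with continuation
#' in chain length) to seed a damped Newton solve of the full nonlinear
#' system, followed by seeded multistart when the seed fails. When
#' root-finding fails everywhere the chain is reported with status
#' `"no_solution"` rather than an error.
#'
#' Two regimes emerge (see [classify_regime()]): for weak sources the canal
#' carries auxin *above* background, increasing along the vein (regime A);
#' for strong sources auxin in the canal falls *below* background and
#' decreases along the vein while the tip cell accumulates (regime B).
#'
#' @param n Number of chain edges (chain of `n + 1` cells); `n = 0` returns
#'   the isolated source.
#' @param alpha,alpha0,beta Background production, source production and
#'   degradation rates (`alpha0 > alpha > 0`, `beta > 0`).
#' @param c PIN capacity (> 0).
#' @param lambda,mu PIN insertion/removal rates; the steady state depends on
#'   them only through `c`, but they fix the membrane-PIN residual scale.
#' @param tol Newton residual tolerance.
#' @param n_starts Multistart attempts after continuation fails.
#' @param seed Seed for the multistart draws.
#' @return A `chain_solution`: list with `cells` (tibble `position` 0..n,
#'   `a`, `p_out`, `J_out`), `regime` (`"A"`, `"B"` or `"other"`),
#'   `degenerate`, `background`, `status` (`"ok"` or `"no_solution"`) and
#'   the parameters.
#' @examples
#' sol <- solve_source_chain(19, alpha = 0.1, alpha0 = 3.1, beta = 0.1, c = 1)
#' sol$regime
#' @export
solve_source_chain <- function(n, alpha, alpha0, beta, c = 1,
                               lambda = 0.01, mu = 0.01, tol = 1e-12,
                               n_starts = 10, seed = 1L) {
  if (!(beta > 0) || !(alpha > 0) || !(alpha0 > alpha)) {
    abort("need `alpha0 > alpha > 0` and `beta > 0`.")
  }
  if (c <= 0) abort("`c` must be positive.")
  background <- alpha / beta
  empty <- function(status) {
    structure(list(
      cells = tibble(position = 0:n, a = NA_real_, p_out = NA_real_,
                     J_out = NA_real_),
      regime = "other", degenerate = FALSE, background = background,
      status = status, n = n, alpha = alpha, alpha0 = alpha0, beta = beta,
      c = c, lambda = lambda, mu = mu), class = "chain_solution")
  }
  if (n == 0) {
    out <- empty("ok")
    out$cells$a <- alpha0 / beta
    return(out)
  }
  upper_root <- function(b) {
    disc <- b^2 - 4 * beta / c
    if (disc < 0) return(NA_real_)
    (b + sqrt(disc)) / 2
  }
  # continuation seed: grow the chain one edge at a time via the recursion
  seed_chain <- function() {
    Jv <- numeric(n)
    Jv[1] <- upper_root(alpha0)
    if (is.na(Jv[1])) return(NULL)
    if (n > 1) {
      for (k in 2:n) {
        Jv[k] <- upper_root(alpha + Jv[k - 1])
        if (is.na(Jv[k])) return(NULL)
      }
    }
    a <- c(1 / (c * Jv), (alpha + Jv[n]) / beta)
    list(a = a, p = c * Jv^2)
  }
  lamP <- c * mu / lambda  # alpha_p / beta_p consistent with (c, lambda, mu)
  resid <- function(x) {
    a <- x[seq_len(n + 1)]
    p <- x[n + 1 + seq_len(n)]
    J <- a[seq_len(n)] * p
    alpha_vec <- c(alpha0, rep(alpha, n))
    bal <- alpha_vec - beta * a - c(J, 0) + c(0, J)
    c(bal, lambda * lamP * rf_eval(response_quadratic(), J) - mu * p)
  }
  sol <- NULL
  sd <- seed_chain()
  if (!is.null(sd)) {
    cand <- damped_newton(resid, c(sd$a, sd$p), tol = tol)
    if (cand$ok && all(cand$x > 0)) sol <- cand
  }
  if (is.null(sol)) {
    starts <- with_local_seed(seed, purrr::map(seq_len(n_starts), function(s) {
      c(runif(n + 1, 0.2, 3) * background, runif(n, 0.01, 2))
    }))
    for (x0 in starts) {
      cand <- damped_newton(resid, x0, tol = tol)
      if (cand$ok && all(cand$x > 0)) { sol <- cand; break }
    }
  }
  if (is.null(sol)) return(empty("no_solution"))
  a <- sol$x[seq_len(n + 1)]
  p <- sol$x[n + 1 + seq_len(n)]
  out <- structure(list(
    cells = tibble(position = 0:n, a = a, p_out = c(p, NA_real_),
                   J_out = c(a[seq_len(n)] * p, NA_real_)),
    regime = "other", degenerate = FALSE, background = background,
    status = "ok", n = n, alpha = alpha, alpha0 = alpha0, beta = beta,
    c = c, lambda = lambda, mu = mu), class = "chain_solution")
  cls <- classify_regime(out)
  out$regime <- cls$regime
  out$degenerate <- cls$degenerate
  out
}

#' @export
print.chain_solution <- function(x, ...) {
  cat(sprintf("<chain_solution> %d edges | status: %s | regime: %s%s | background = %g\n",
              x$n, x$status, x$regime,
              if (x$degenerate) " (degenerate)" else "", x$background))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.chain_solution <- function(x, ...) x$cells

#' @exportS3Method generics::glance
glance.chain_solution <- function(x, ...) {
  tibble(n = x$n, status = x$status, regime = x$regime,
         degenerate = x$degenerate, background = x$background,
         alpha = x$alpha, alpha0 = x$alpha0, beta = x$beta, c = x$c)
}

#' Classify a source-driven vein profile
#'
#' Regime `A`: auxin is at or above the background `alpha/beta` at the
#' source and nondecreasing along the vein (flux along the auxin gradient,
#' canal richer than the surroundings). Regime `B`: the reversed chain of
#' inequalities (flux against the gradient, canal poorer than the
#' surroundings). Anything else is `"other"`. A constant profile at exactly
#' the background level satisfies both chains; it is reported as `A` with
#' `degenerate = TRUE` (deterministic tie-break).
#'
#' For a `chain_solution` the inequalities are tested over the vein *body* -
#' the cells that pump auxin onward. The terminal cell of a finite chain is
#' a sink whose balance `a_n = (alpha + J) / beta` makes it accumulate
#' regardless of regime, so including it would mislabel every against-
#' gradient vein (the published decreasing-canal profile is likewise stated
#' over the pumping cells only). A bare numeric profile is classified
#' exactly as given.
#'
#' @param chain A `chain_solution`, or a bare numeric auxin profile.
#' @param background Background level `alpha/beta` (taken from the
#'   `chain_solution` when available).
#' @param tol Tolerance on the inequalities.
#' @return A list with `regime` and `degenerate`.
#' @export
classify_regime <- function(chain, background = NULL, tol = 1e-8) {
  a <- if (inherits(chain, "chain_solution")) {
    # vein body: drop the accumulating terminal sink of a finite chain
    if (chain$n >= 2) head(chain$cells$a, -1) else chain$cells$a
  } else {
    as.double(chain)
  }
  background <- background %||%
    (if (inherits(chain, "chain_solution")) chain$background else
      abort("`background` is required for a bare profile."))
  if (anyNA(a)) return(list(regime = "other", degenerate = FALSE))
  up <- all(diff(a) >= -tol) && a[1] >= background - tol
  down <- all(diff(a) <= tol) && a[1] <= background + tol
  if (up && down) return(list(regime = "A", degenerate = TRUE))
  if (up) return(list(regime = "A", degenerate = FALSE))
  if (down) return(list(regime = "B", degenerate = FALSE))
  list(regime = "other", degenerate = FALSE)
}

#' Regime map over a source/background production grid
#'
#' Solves the source-driven vein for every `(alpha, alpha0)` pair on a grid
#' and records the regime. By default the longest admissible vein not
#' exceeding `n` edges is classified (regime-A veins have a finite maximal
#' length, so insisting on exactly `n` edges would relabel short-vein
#' parameter points as failures); points with `alpha0 <= alpha` or no vein
#' at all are labelled `"other"`.
#'
#' @param alpha,alpha0 Grid vectors of background and source production
#'   rates.
#' @param c,lambda,mu,beta Remaining parameters (scalars).
#' @param n Maximum vein length (edges).
#' @param shrink Fall back to shorter veins when the length-`n` chain has no
#'   solution?
#' @return A `regime_map` tibble: `alpha`, `alpha0`, `regime`, `n_used`.
#' @export
regime_map <- function(alpha, alpha0, c = 1, lambda = 0.01, mu = 0.01,
                       beta = 0.1, n = 3, shrink = TRUE) {
  stopifnot(all(is.finite(alpha)), all(is.finite(alpha0)),
            all(alpha > 0), all(alpha0 > 0), beta > 0, c > 0)
  grid <- tidyr::expand_grid(alpha = alpha, alpha0 = alpha0)
  res <- purrr::pmap(grid, function(alpha, alpha0) {
    if (alpha0 <= alpha) return(list(regime = "other", n_used = NA_integer_))
    for (nn in seq.int(n, 1L)) {
      sol <- solve_source_chain(nn, alpha, alpha0, beta, c, lambda, mu)
      if (sol$status == "ok" && sol$regime != "other") {
        return(list(regime = sol$regime, n_used = nn))
      }
      if (!shrink) break
    }
    list(regime = "other", n_used = NA_integer_)
  })
  out <- grid
  out$regime <- map_chr(res, "regime")
  out$n_used <- vapply(res, function(r) as.integer(r$n_used %||% NA), 1L)
  class(out) <- c("regime_map", class(out))
  out
}
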