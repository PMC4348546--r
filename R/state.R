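#' Model state
#'
#' A state holds the auxin concentration `a_i` per cell, optionally the
#' cytosolic PIN `P_i` per cell (extended variant only), and the membrane PIN
#' `p_ij` per *ordered* adjacent pair, aligned with `tissue$pairs` (so each
#' undirected edge carries two independent values, `p_ij` and `p_ji`). All
#' entries must be nonnegative on construction.
#'
#' @param tissue A [tissue_graph()].
#' @param a Auxin concentrations (recycled to the number of cells).
#' @param p Membrane PIN (recycled to the number of ordered pairs).
#' @param P Cytosolic PIN (recycled to cells), or `NULL` when not modelled.
#' @return A `flux_state` object.
#' @export
flux_state <- function(tissue, a, p = 0, P = NULL) {
  stopifnot(inherits(tissue, "tissue_graph"))
  a <- rep_len(as.double(a), tissue$n_cells)
  p <- rep_len(as.double(p), nrow(tissue$pairs))
  if (!is.null(P)) P <- rep_len(as.double(P), tissue$n_cells)
  vals <- c(a, P, p)
  if (any(!is.finite(vals))) abort("state entries must be finite.")
  if (any(vals < 0)) abort("state entries must be nonnegative.")
  structure(list(a = a, P = P, p = p), class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat(sprintf("<flux_state> %d cells%s, %d membrane faces | a in [%g, %g], max p = %g\n",
              length(x$a), if (is.null(x$P)) "" else " (+cytosolic PIN)",
              length(x$p), min(x$a), max(x$a), if (length(x$p)) max(x$p) else 0))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.flux_state <- function(x, tissue = NULL, ...) {
  out <- tibble(variable = "a", index = seq_along(x$a),
                i = seq_along(x$a), j = NA_integer_, value = x$a)
  if (!is.null(x$P)) {
    out <- bind_rows(out, tibble(variable = "P", index = seq_along(x$P),
                                 i = seq_along(x$P), j = NA_integer_, value = x$P))
  }
  if (length(x$p)) {
    ij <- if (!is.null(tissue)) tissue$pairs else NULL
    out <- bind_rows(out, tibble(
      variable = "p", index = seq_along(x$p),
      i = if (is.null(ij)) NA_integer_ else ij$i,
      j = if (is.null(ij)) NA_integer_ else ij$j,
      value = x$p
    ))
  }
  out
}

#' Random nonnegative state
#'
#' Seeded uniform random state generator for property tests.
#'
#' @param tissue A [tissue_graph()].
#' @param seed Integer seed.
#' @param scale Upper bound of the uniform draws.
#' @param cytosolic Include a cytosolic PIN component?
#' @return A [flux_state()].
#' @export
random_state <- function(tissue, seed = 1L, scale = 1, cytosolic = FALSE) {
  n <- tissue$n_cells
  np <- nrow(tissue$pairs)
  vals <- with_local_seed(seed, runif(2 * n + np, 0, scale))
  flux_state(tissue,
             a = vals[seq_len(n)],
             P = if (cytosolic) vals[n + seq_len(n)] else NULL,
             p = vals[2 * n + seq_len(np)])
}

# ---- packing between flux_state and deSolve's flat vector ----------------
pack_state <- function(state) c(state$a, state$P, state$p)

unpack_state <- function(y, tissue, cytosolic = FALSE) {
  y <- unname(y)
  n <- tissue$n_cells
  np <- nrow(tissue$pairs)
  if (cytosolic) {
    list(a = y[seq_len(n)], P = y[n + seq_len(n)], p = y[2 * n + seq_len(np)])
  } else {
    list(a = y[seq_len(n)], P = NULL, p = y[n + seq_len(np)])
  }
}

state_names <- function(tissue, cytosolic = FALSE) {
  p_names <- if (nrow(tissue$pairs)) {
    paste0("p", tissue$pairs$i, "_", tissue$pairs$j)
  } else character(0)
  c(paste0("a", seq_len(tissue$n_cells)),
    if (cytosolic) paste0("P", seq_len(tissue$n_cells)),
    p_names)
}
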