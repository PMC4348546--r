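#' Extract the steady-state orientation graph
#'
#' At any equilibrium of the slow-PIN model the rectified response forces
#' complementarity on every membrane: at least one of `p_ij*`, `p_ji*`
#' vanishes. Each steady state therefore orients the tissue graph: the edge
#' `i ~ j` becomes `i -> j` when `p_ij* > tol >= p_ji*`, is dropped when both
#' faces are (numerically) zero, and violates the equilibrium structure when
#' both exceed the threshold. Cells left with no incident oriented edge form
#' the isolated set `I*`; the remaining cells `V*` carry the vascular
#' pattern.
#'
#' @param state A [flux_state()] at (approximate) equilibrium; the caller is
#'   responsible for the equilibrium precondition (e.g. a converged
#'   [simulate_flux()] run).
#' @param tissue A [tissue_graph()].
#' @param tol Absolute threshold below which a membrane PIN counts as zero.
#'   The default is relative to the largest PIN present,
#'   `1e-6 * max(1, max(p))`, so it survives unit rescaling.
#' @return A `pin_orientation` object: list with `edges` (tibble `from`,
#'   `to`, `p`, `J` where `J` is the active flux along the oriented edge),
#'   `isolated`, `retained`, `n_cells` and `a` (the auxin profile, kept for
#'   reporting/plotting).
#' @export
extract_orientation <- function(state, tissue, tol = NULL) {
  check_state_dims(state, tissue, cytosolic = !is.null(state$P))
  p <- state$p
  tol <- tol %||% (1e-6 * max(1, if (length(p)) max(p) else 0))
  pr <- tissue$pairs
  fwd <- p > tol
  viol <- fwd & fwd[pr$rev]
  if (any(viol)) {
    bad <- pr[viol & pr$i < pr$j, , drop = FALSE]
    abort(paste0(
      "not a valid slow-model equilibrium orientation: both membrane faces ",
      "carry PIN above tol on edge(s) ",
      paste(sprintf("%d~%d", bad$i, bad$j), collapse = ", "), "."))
  }
  keep <- which(fwd)
  edges <- tibble(
    from = pr$i[keep], to = pr$j[keep], p = p[keep],
    J = state$a[pr$i[keep]] * p[keep]    # opposite face is (numerically) zero
  )
  touched <- unique(c(edges$from, edges$to))
  structure(
    list(edges = edges, isolated = setdiff(seq_len(tissue$n_cells), touched),
         retained = sort(touched), n_cells = tissue$n_cells, a = state$a,
         tol = tol),
    class = "pin_orientation")
}

#' Construct an orientation directly
#'
#' Builds a `pin_orientation` from an explicit directed edge list, for
#' prescribing steady-state supports (e.g. a cycle or an in-tree) to
#' [construct_equilibrium()] and [solve_sink_tree()].
#'
#' @param edges Two-column matrix/data frame of directed edges `from -> to`.
#' @param n_cells Total number of cells.
#' @param p,J Optional per-edge attributes.
#' @param a Optional auxin profile.
#' @export
orientation <- function(edges, n_cells, p = NA_real_, J = NA_real_, a = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0) edges <- matrix(integer(0), ncol = 2)
  ed <- tibble(from = as.integer(edges[, 1]), to = as.integer(edges[, 2]),
               p = rep_len(as.double(p), nrow(edges)),
               J = rep_len(as.double(J), nrow(edges)))
  und <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  if (anyDuplicated(und)) {
    abort("an orientation carries at most one direction per undirected edge.")
  }
  touched <- unique(c(ed$from, ed$to))
  structure(
    list(edges = ed, isolated = setdiff(seq_len(n_cells), touched),
         retained = sort(touched), n_cells = n_cells, a = a, tol = 0),
    class = "pin_orientation")
}

#' @export
print.pin_orientation <- function(x, ...) {
  cat(sprintf("<pin_orientation> %d oriented edges, %d retained / %d isolated cells\n",
              nrow(x$edges), length(x$retained), length(x$isolated)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pin_orientation <- function(x, ...) x$edges

as_igraph_orientation <- function(orient, drop_isolated = TRUE) {
  n <- if (drop_isolated) orient$n_cells else orient$n_cells
  g <- igraph::make_empty_graph(n = orient$n_cells, directed = TRUE)
  if (nrow(orient$edges)) {
    g <- igraph::add_edges(g, rbind(orient$edges$from, orient$edges$to))
    igraph::E(g)$p <- orient$edges$p
    igraph::E(g)$J <- orient$edges$J
  }
  if (!is.null(orient$a)) igraph::V(g)$a <- orient$a
  g
}

#' Classify the topology of an orientation
#'
#' Computes degrees, sinks (out-degree 0, in-degree > 0), sources (in-degree
#' 0, out-degree > 0), cycles, and the sink-rooted-forest property (acyclic
#' with every out-degree <= 1) of a steady-state orientation, and issues the
#' necessary-condition verdict for stability of the underlying equilibrium
#' under a quadratic response: an orientation with no sink, a directed
#' cycle, or a cell of out-degree > 1 belongs to an unstable equilibrium
#' (`"certified_unstable"`); otherwise the necessary conditions hold
#' (`"necessary_conditions_met"`). The verdict is a falsifier only - it
#' never certifies stability; spectral claims come from
#' [jacobian_stability()].
#'
#' @param orient A `pin_orientation`.
#' @return A `topology_report`: list with `nodes` (tibble `cell`, `in_deg`,
#'   `out_deg`), `sinks`, `sources`, `has_cycle`, `is_sink_rooted_forest`
#'   and `verdict`. Degree bookkeeping covers the retained cells; isolated
#'   cells take no part in the verdict.
#' @export
classify_topology <- function(orient) {
  stopifnot(inherits(orient, "pin_orientation"))
  n <- orient$n_cells
  out_deg <- tabulate(orient$edges$from, nbins = n)
  in_deg <- tabulate(orient$edges$to, nbins = n)
  nodes <- tibble(cell = seq_len(n), in_deg = in_deg, out_deg = out_deg)
  sinks <- which(out_deg == 0 & in_deg > 0)
  sources <- which(in_deg == 0 & out_deg > 0)
  has_cycle <- if (nrow(orient$edges)) {
    !igraph::is_dag(as_igraph_orientation(orient))
  } else FALSE
  forest <- !has_cycle && all(out_deg <= 1)
  retained <- nodes$in_deg + nodes$out_deg > 0
  verdict <- if (any(retained) &&
                 (length(sinks) == 0 || has_cycle || any(out_deg > 1))) {
    "certified_unstable"
  } else {
    "necessary_conditions_met"
  }
  structure(
    list(nodes = nodes, sinks = sinks, sources = sources,
         has_cycle = has_cycle, is_sink_rooted_forest = forest,
         verdict = verdict),
    class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("<topology_report> sinks: %s | sources: %s | cycle: %s | sink-rooted forest: %s\n  verdict: %s\n",
              paste(x$sinks, collapse = ","), paste(x$sources, collapse = ","),
              x$has_cycle, x$is_sink_rooted_forest, x$verdict))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.topology_report <- function(x, ...) {
  tibble(n_sinks = length(x$sinks), n_sources = length(x$sources),
         has_cycle = x$has_cycle,
         is_sink_rooted_forest = x$is_sink_rooted_forest,
         max_out_deg = max(x$nodes$out_deg), verdict = x$verdict)
}

#' Export an orientation to GraphML or DOT
#'
#' Nodes carry the steady auxin `a`, edges the membrane PIN `p` and flux `J`.
#' GraphML files re-import exactly via [import_orientation()].
#'
#' @param orient A `pin_orientation`.
#' @param path Output file.
#' @param format `"graphml"` or `"dot"`.
#' @export
export_orientation <- function(orient, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  g <- as_igraph_orientation(orient)
  if (is.null(orient$a)) igraph::V(g)$a <- NA_real_
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' @rdname export_orientation
#' @export
import_orientation <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g, names = FALSE)
  att <- igraph::edge_attr(g)
  a <- igraph::vertex_attr(g, "a")
  orientation(el, n_cells = igraph::vcount(g),
              p = att$p %||% NA_real_, J = att$J %||% NA_real_,
              a = if (!is.null(a) && !all(is.na(a))) a else NULL)
}
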