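#' Exact sink-driven steady state on an in-tree
#'
#' In the sink-driven setting a single cell `i0` (the root) degrades auxin
#' (`beta_a(i0) > 0`) while every other cell only produces it. The steady
#' orientation is then a spanning in-tree rooted at `i0` and the slow-PIN
#' steady state is exact: the flux out of each non-root cell equals the
#' cumulative production `A(i) = sum of alpha_a over the sub-tree draining
#' through i` (one post-order pass), so
#' `a_i = 1 / (c * A(i))` for `i != i0` and `a_(i0) = A(i0) / beta_a(i0)`,
#' with membrane PIN `p = c * A(i)^2` on the tree edge out of `i`. Since the
#' subtree sums grow along every path into the root, auxin *decreases*
#' along the paths: the flux runs against the auxin gradient and a depleted
#' zone surrounds the sink.
#'
#' @param tree A [orientation()]: a spanning in-tree (every non-root cell
#'   has out-degree exactly 1, acyclic) over its node set.
#' @param alpha_a Per-cell auxin production rates (length `n_cells`).
#' @param c PIN capacity `lambda * alpha_p / (mu * beta_p)` (> 0).
#' @param beta_root Auxin degradation rate of the root (> 0).
#' @return A tibble with one row per cell: `cell`, `a` (steady auxin),
#'   `subtree_production` (`A(i)`), `p_out` and `J_out` (membrane PIN and
#'   flux on the edge toward the root; `NA` for the root), `is_root`.
#' @examples
#' tr <- orientation(rbind(c(1, 2), c(2, 3)), n_cells = 3)
#' solve_sink_tree(tr, alpha_a = c(1, 1, 1), c = 1, beta_root = 1)
#' @export
solve_sink_tree <- function(tree, alpha_a, c = 1, beta_root) {
  stopifnot(inherits(tree, "pin_orientation"))
  if (c <= 0) abort("`c` must be positive.")
  if (beta_root <= 0) abort("no steady state: the root must degrade auxin (`beta_root > 0`).")
  n <- tree$n_cells
  alpha_a <- rep_len(as.double(alpha_a), n)
  ed <- tree$edges
  out_deg <- tabulate(ed$from, nbins = n)
  root <- which(out_deg == 0)
  if (length(root) != 1 || any(out_deg > 1) || nrow(ed) != n - 1) {
    abort("`tree` is not a spanning in-tree: need exactly one root and out-degree 1 elsewhere.")
  }
  g <- as_igraph_orientation(tree)
  if (!igraph::is_dag(g)) abort("`tree` contains a directed cycle.")
  parent <- rep(NA_integer_, n)
  parent[ed$from] <- ed$to
  # post-order accumulation: deepest cells first
  depth <- vapply(seq_len(n), function(v) {
    d <- 0L
    while (v != root) { v <- parent[v]; d <- d + 1L }
    d
  }, 1L)
  A <- alpha_a
  for (v in order(-depth)) {
    if (v != root) A[parent[v]] <- A[parent[v]] + A[v]
  }
  a <- 1 / (c * A)
  a[root] <- A[root] / beta_root
  p_out <- rep(NA_real_, n)
  J_out <- rep(NA_real_, n)
  nr <- seq_len(n) != root
  J_out[nr] <- A[nr]
  p_out[nr] <- c * A[nr]^2
  tibble(cell = seq_len(n), a = a, subtree_production = A,
         p_out = p_out, J_out = J_out, is_root = seq_len(n) == root)
}

#' Embed a sink-tree solution as a model state
#'
#' @param tree The in-tree passed to [solve_sink_tree()].
#' @param solution The tibble it returned.
#' @param tissue A [tissue_graph()] containing the tree edges.
#' @return A [flux_state()] that is an exact slow-PIN equilibrium.
#' @export
sink_tree_state <- function(tree, solution, tissue) {
  pr <- tissue$pairs
  key <- paste(pr$i, pr$j)
  nr <- !solution$is_root
  # out-edges: from cell to its parent
  parent <- rep(NA_integer_, tree$n_cells)
  parent[tree$edges$from] <- tree$edges$to
  slot <- match(paste(solution$cell[nr], parent[solution$cell[nr]]), key)
  if (anyNA(slot)) abort("tree edges missing from the tissue graph.")
  p <- rep(0, nrow(pr))
  p[slot] <- solution$p_out[nr]
  flux_state(tissue, a = solution$a, p = p)
}

#' Random rooted in-tree
#'
#' Uniformly sampled labelled tree (Pruefer decoding) with a uniformly
#' chosen root, every edge oriented toward the root. Seed-deterministic.
#'
#' @param n_nodes Number of nodes (>= 1).
#' @param seed Integer seed.
#' @return A [orientation()] whose edges all point toward the root
#'   (attribute-free); the root is the unique node with out-degree 0.
#' @export
random_in_tree <- function(n_nodes, seed = 1L) {
  stopifnot(n_nodes >= 1)
  if (n_nodes == 1) return(orientation(matrix(integer(0), ncol = 2), 1))
  with_local_seed(seed, {
    root <- sample.int(n_nodes, 1)
    if (n_nodes == 2) {
      el <- matrix(c(setdiff(1:2, root), root), ncol = 2)
      return(orientation(el, 2))
    }
    pruefer <- sample.int(n_nodes, n_nodes - 2, replace = TRUE)
    deg <- rep(1L, n_nodes)
    for (x in pruefer) deg[x] <- deg[x] + 1L
    edges <- matrix(0L, n_nodes - 1, 2)
    avail <- deg
    r <- 1L
    for (x in pruefer) {
      leaf <- which(avail == 1L)[1]
      edges[r, ] <- c(leaf, x); r <- r + 1L
      avail[leaf] <- 0L; avail[x] <- avail[x] - 1L
    }
    edges[r, ] <- which(avail == 1L)
    # orient toward the chosen root by BFS from the root
    adj <- vector("list", n_nodes)
    for (q in seq_len(n_nodes - 1)) {
      aa <- edges[q, 1]; bb <- edges[q, 2]
      adj[[aa]] <- c(adj[[aa]], bb); adj[[bb]] <- c(adj[[bb]], aa)
    }
    parent <- rep(NA_integer_, n_nodes); parent[root] <- 0L
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(parent[w])) {
        parent[w] <- v; queue <- c(queue, w)
      }
    }
    nonroot <- setdiff(seq_len(n_nodes), root)
    orientation(cbind(nonroot, parent[nonroot]), n_nodes)
  })
}
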