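#' Build a tissue graph
#'
#' A tissue graph is the substrate of every model variant: cells are nodes,
#' and two cells share an edge when they are adjacent, i.e. when auxin can be
#' exchanged across the membrane that separates them. Each cell `i` carries a
#' volume `V_i` (m^3) and each undirected edge an interface area `S_ij`
#' (m^2); both default to 1 (dimensionless working units). Membrane PIN lives
#' on *ordered* adjacent pairs: every undirected edge contributes two directed
#' membrane faces, `(i, j)` and `(j, i)`, with independent PIN values.
#'
#' @param edges A two-column matrix or data frame of undirected edges
#'   (cell indices). Each pair must appear once; self-edges are rejected.
#' @param n_cells Number of cells. Defaults to the largest index in `edges`.
#' @param volumes Cell volumes, recycled to `n_cells`. Must be positive.
#' @param areas Interface areas, one per undirected edge (recycled). Positive.
#' @param coords Optional two-column matrix of plotting coordinates per cell.
#'
#' @return A `tissue_graph` object: a list with tibbles `cells`
#'   (`cell`, `volume`, `x`, `y`), `edges` (`edge`, `from`, `to`, `area`) and
#'   `pairs` (one row per ordered adjacent pair: `pair`, `i`, `j`, `edge`,
#'   `rev`, where `rev` indexes the opposite face), plus the scalars
#'   `n_cells`, `regular` (all volumes equal and all areas equal) and `W`
#'   (the surface-to-volume ratio `S/V`, defined when regular).
#' @examples
#' tg <- tissue_graph(rbind(c(1, 2), c(2, 3)))
#' tg$regular
#' make_grid(2, 3)$n_cells
#' @export
tissue_graph <- function(edges, n_cells = NULL, volumes = 1, areas = 1,
                         coords = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0) {
    edges <- matrix(integer(0), ncol = 2)
  }
  if (ncol(edges) != 2) abort("`edges` must have two columns.")
  dimnames(edges) <- NULL
  storage.mode(edges) <- "integer"
  if (any(edges[, 1] == edges[, 2])) abort("self-edges are not allowed.")
  n_cells <- as.integer(n_cells %||% max(1L, edges))
  if (nrow(edges) > 0 && max(edges) > n_cells) {
    abort("edge endpoint exceeds `n_cells`.")
  }
  # canonical (min, max) form; adjacency is symmetric by construction
  e <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  if (anyDuplicated(paste(e[, 1], e[, 2]))) abort("duplicated edges.")
  m <- nrow(e)
  volumes <- rep_len(as.double(volumes), n_cells)
  areas <- rep_len(as.double(areas), max(m, 1L))[seq_len(m)]
  if (any(volumes <= 0)) abort("cell volumes must be positive.")
  if (m > 0 && any(areas <= 0)) abort("interface areas must be positive.")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == n_cells, ncol(coords) == 2)
  } else {
    coords <- matrix(NA_real_, n_cells, 2)
  }
  cells <- tibble(cell = seq_len(n_cells), volume = volumes,
                  x = coords[, 1], y = coords[, 2])
  edges_tbl <- tibble(edge = seq_len(m), from = as.integer(e[, 1]),
                      to = as.integer(e[, 2]), area = areas)
  pairs <- tibble(
    pair = seq_len(2L * m),
    i = c(e[, 1], e[, 2]),
    j = c(e[, 2], e[, 1]),
    edge = rep(seq_len(m), 2L),
    rev = c(seq_len(m) + m, seq_len(m))
  )
  regular <- (n_cells <= 1 || diff(range(volumes)) == 0) &&
    (m == 0 || diff(range(areas)) == 0)
  W <- if (regular && m > 0) areas[1] / volumes[1] else if (regular) 1 else NA_real_
  structure(
    list(cells = cells, edges = edges_tbl, pairs = pairs,
         n_cells = n_cells, n_edges = m, regular = regular, W = W),
    class = "tissue_graph"
  )
}

#' @export
print.tissue_graph <- function(x, ...) {
  cat(sprintf("<tissue_graph> %d cells, %d edges (%s)\n", x$n_cells, x$n_edges,
              if (x$regular) sprintf("regular, W = %g", x$W) else "non-regular"))
  invisible(x)
}

#' Neighbour sets and degrees
#'
#' @param tissue A [tissue_graph()].
#' @return `cell_degrees()` returns a tibble with one row per cell and its
#'   degree; `neighbours()` returns the integer vector of cells adjacent to
#'   `cell`.
#' @export
cell_degrees <- function(tissue) {
  deg <- tabulate(tissue$pairs$i, nbins = tissue$n_cells)
  tibble(cell = seq_len(tissue$n_cells), degree = deg)
}

#' @rdname cell_degrees
#' @param cell A cell index.
#' @export
neighbours <- function(tissue, cell) {
  sort(tissue$pairs$j[tissue$pairs$i == cell])
}

#' Rectangular grid tissue
#'
#' 4-neighbour lattice without periodic wrap, the substrate used for the
#' grid canalization experiments. With `regular = FALSE`, volumes and areas
#' are jittered by +/-10% around 1 (seeded), emulating a grid of non-regular
#' cells.
#'
#' @param rows,cols Grid dimensions (>= 1).
#' @param regular If `TRUE` all volumes and areas are 1.
#' @param seed Seed for the non-regular jitter.
#' @return A [tissue_graph()] with row-major cell indexing and grid coords.
#' @export
make_grid <- function(rows, cols, regular = TRUE, seed = 1L) {
  stopifnot(rows >= 1, cols >= 1)
  id <- function(r, c) (r - 1L) * cols + c
  from <- integer(0); to <- integer(0)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      if (c < cols) { from <- c(from, id(r, c)); to <- c(to, id(r, c + 1L)) }
      if (r < rows) { from <- c(from, id(r, c)); to <- c(to, id(r + 1L, c)) }
    }
  }
  n <- rows * cols
  coords <- cbind(rep(seq_len(cols), times = rows),
                  rep(rev(seq_len(rows)), each = cols))
  if (regular) {
    tissue_graph(cbind(from, to), n_cells = n, coords = coords)
  } else {
    m <- length(from)
    jit <- with_local_seed(seed, runif(n + m, -0.1, 0.1))
    tissue_graph(cbind(from, to), n_cells = n,
                 volumes = 1 + jit[seq_len(n)], areas = 1 + jit[n + seq_len(m)],
                 coords = coords)
  }
}

#' Line tissue
#'
#' Path graph of `L` cells (the 1-D setting of the source- and sink-driven
#' experiments). `periodic = TRUE` closes the ring.
#'
#' @param L Number of cells (>= 2).
#' @param periodic Close the line into a ring?
#' @return A [tissue_graph()].
#' @export
make_line <- function(L, periodic = FALSE) {
  stopifnot(L >= 2)
  from <- seq_len(L - 1L); to <- from + 1L
  if (periodic) { from <- c(from, L); to <- c(to, 1L) }
  tissue_graph(cbind(from, to), n_cells = L,
               coords = cbind(seq_len(L), rep(0, L)))
}

#' Convert a tissue graph to an igraph object
#'
#' @param tissue A [tissue_graph()].
#' @return An undirected `igraph` graph with `volume` vertex and `area` edge
#'   attributes.
#' @export
as_igraph <- function(tissue) {
  g <- igraph::make_empty_graph(n = tissue$n_cells, directed = FALSE)
  if (tissue$n_edges > 0) {
    g <- igraph::add_edges(g, rbind(tissue$edges$from, tissue$edges$to))
  }
  igraph::V(g)$volume <- tissue$cells$volume
  if (tissue$n_edges > 0) igraph::E(g)$area <- tissue$edges$area
  g
}

#' Serialize a tissue graph to and from JSON
#'
#' The JSON document stores cells (with volumes and optional coordinates) and
#' edges (with areas); `tissue_from_json(tissue_to_json(x))` reproduces `x`.
#'
#' @param tissue A [tissue_graph()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @export
tissue_to_json <- function(tissue, path = NULL) {
  doc <- list(
    cells = tissue$cells,
    edges = tissue$edges[c("from", "to", "area")]
  )
  txt <- jsonlite::toJSON(doc, digits = NA, na = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname tissue_to_json
#' @param json A JSON string or file path produced by [tissue_to_json()].
#' @export
tissue_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  cells <- as_tibble(doc$cells)
  edges <- as_tibble(doc$edges)
  coords <- if (all(c("x", "y") %in% names(cells)) && !all(is.na(cells$x))) {
    cbind(cells$x, cells$y)
  } else NULL
  tissue_graph(cbind(edges$from, edges$to), n_cells = nrow(cells),
               volumes = cells$volume,
               areas = if (nrow(edges)) edges$area else 1,
               coords = coords)
}

#' Export the adjacency of a tissue graph
#'
#' @param tissue A [tissue_graph()].
#' @param path Output file.
#' @param format `"graphml"` or `"dot"`.
#' @export
export_tissue <- function(tissue, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(as_igraph(tissue), path, format = format)
  invisible(path)
}

# run `expr` under a temporary RNG state; never leaks into the caller's RNG
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
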