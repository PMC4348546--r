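#' Plot methods
#'
#' `autoplot()` methods for the main result types: auxin trajectories for a
#' simulation, the auxin profile along a vein for a chain solution, the
#' regime partition for a regime map, and the oriented vascular pattern for
#' an orientation on a tissue with coordinates.
#'
#' @param object The object to plot.
#' @param variables Which state variables to draw (`"a"`, `"p"`, `"P"`).
#' @param ... Unused.
#' @return A `ggplot` object.
#' @name autoplot-fluxcanal
NULL

#' @rdname autoplot-fluxcanal
#' @exportS3Method ggplot2::autoplot
autoplot.flux_sim <- function(object, variables = "a", ...) {
  dat <- tidy(object) |>
    filter(.data$variable %in% variables) |>
    mutate(series = paste0(.data$variable, .data$i,
                           ifelse(is.na(.data$j), "", paste0("_", .data$j))))
  ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$value,
                                    group = .data$series,
                                    colour = factor(.data$i))) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time", y = "concentration") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-fluxcanal
#' @exportS3Method ggplot2::autoplot
autoplot.chain_solution <- function(object, ...) {
  ggplot2::ggplot(object$cells, ggplot2::aes(.data$position, .data$a)) +
    ggplot2::geom_hline(yintercept = object$background, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "position along vein (source = 0)", y = "steady auxin",
                  title = sprintf("regime %s vein", object$regime)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-fluxcanal
#' @exportS3Method ggplot2::autoplot
autoplot.regime_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$alpha, .data$alpha0,
                                       fill = .data$regime)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(A = "#2e7d32", B = "grey40",
                                          other = "grey90")) +
    ggplot2::labs(x = "background production alpha",
                  y = "source production alpha0") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-fluxcanal
#' @param tissue The [tissue_graph()] supplying cell coordinates.
#' @exportS3Method ggplot2::autoplot
autoplot.pin_orientation <- function(object, tissue, ...) {
  if (all(is.na(tissue$cells$x))) {
    abort("the tissue has no plotting coordinates.")
  }
  nodes <- tissue$cells
  if (!is.null(object$a)) nodes$a <- object$a
  seg <- object$edges |>
    left_join(nodes, by = c(from = "cell")) |>
    left_join(nodes, by = c(to = "cell"), suffix = c("", "_to"))
  gp <- ggplot2::ggplot(nodes, ggplot2::aes(.data$x, .data$y))
  gp <- if (is.null(object$a)) gp + ggplot2::geom_point(size = 3) else
    gp + ggplot2::geom_point(ggplot2::aes(colour = .data$a), size = 3) +
    ggplot2::scale_colour_gradient(low = "#e8f5e9", high = "#1b5e20")
  if (nrow(seg)) {
    gp <- gp + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_to,
                   yend = .data$y_to, linewidth = .data$p),
      arrow = grid::arrow(length = grid::unit(2, "mm")), colour = "#b71c1c",
      inherit.aes = FALSE) +
      ggplot2::scale_linewidth(range = c(0.3, 1.5))
  }
  gp + ggplot2::coord_equal() + ggplot2::theme_void()
}
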