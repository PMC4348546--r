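#' Tidy a simulation trajectory
#'
#' @param x A `flux_sim`.
#' @param ... Unused.
#' @return A long tibble with columns `time`, `variable` (`"a"`, `"P"` or
#'   `"p"`), `i`, `j` (`NA` for cell variables) and `value`.
#' @exportS3Method generics::tidy
tidy.flux_sim <- function(x, ...) {
  tissue <- x$tissue
  cyt <- x$variant == "extended"
  n <- tissue$n_cells
  np <- nrow(tissue$pairs)
  cols <- tibble(
    variable = c(rep("a", n), if (cyt) rep("P", n), rep("p", np)),
    i = c(seq_len(n), if (cyt) seq_len(n), tissue$pairs$i),
    j = c(rep(NA_integer_, n * (1 + cyt)), tissue$pairs$j)
  )
  nt <- length(x$times)
  tibble(time = rep(x$times, each = nrow(cols)),
         variable = rep(cols$variable, nt),
         i = rep(cols$i, nt), j = rep(cols$j, nt),
         value = as.vector(t(x$trajectory)))
}

#' @exportS3Method generics::glance
glance.flux_sim <- function(x, ...) {
  tibble(status = x$status, t_end = max(x$times), rhs_norm = x$rhs_norm,
         escape_time = x$escape_time,
         min_a = min(x$final_state$a), max_a = max(x$final_state$a),
         max_p = if (length(x$final_state$p)) max(x$final_state$p) else 0)
}

#' @exportS3Method generics::tidy
tidy.regime_map <- function(x, ...) as_tibble(x)
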