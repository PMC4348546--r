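# shared helpers for the test suite ---------------------------------------

# triangle tissue (3-cycle substrate)
triangle_tissue <- function() {
  tissue_graph(rbind(c(1, 2), c(2, 3), c(1, 3)))
}

# 3-cell star tissue 2 - 1 - 3 (cell 1 in the middle)
star_tissue <- function() {
  tissue_graph(rbind(c(1, 2), c(1, 3)))
}

# parameters for the sink-driven random-tree ensemble: c = 1 with PIN
# turnover slower than auxin turnover (in-tree equilibria are attracting
# in this regime; see the methods vignette)
tree_params <- function(alpha_a, root, n) {
  beta <- rep(0, n); beta[root] <- 1
  model_params(alpha_a = alpha_a, beta_a = beta, mu = 0.1, lambda = 0.1,
               alpha_p = 1, beta_p = 1)
}

# random production rates in [0.5, 2]
random_alpha <- function(n, seed) {
  withr::with_seed(seed, runif(n, 0.5, 2))
}

# the two-cell configuration with strong PIN feedback that escapes in
# finite time under a quadratic response (and cannot under a bounded one)
blowup_setup <- function() {
  list(tissue = make_line(2),
       params = model_params(alpha_a = 1, beta_a = 1, mu = 1, lambda = 1,
                             alpha_p = 100, beta_p = 1),
       init_a = c(2, 0.5),
       init_p = c(1, 0))
}

run_blowup <- function(threshold = 1e6, rtol = 1e-10, atol = 1e-12) {
  bu <- blowup_setup()
  simulate_flux("slow", bu$tissue, bu$params, response_quadratic(),
                flux_state(bu$tissue, a = bu$init_a, p = bu$init_p),
                integrator_options(t_max = 5, rtol = rtol, atol = atol,
                                   blowup_threshold = threshold,
                                   n_chunks = 200))
}

# root of an in-tree orientation (unique node with out-degree 0)
tree_root <- function(tree) {
  which(tabulate(tree$edges$from, nbins = tree$n_cells) == 0)
}

# tissue containing the undirected support of an orientation
tissue_of_orientation <- function(orient) {
  tissue_graph(cbind(orient$edges$from, orient$edges$to),
               n_cells = orient$n_cells)
}
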