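# Run configuration, reporting and manifests -------------------------------

config_schema <- function() {
  list(
    scenario = c("name", "args"),
    tissue = NULL,          # JSON document as produced by tissue_to_json()
    variant = NULL,
    params = c("alpha_a", "beta_a", "gamma_D", "gamma_A", "rho0", "mu",
               "lambda", "alpha_p", "beta_p"),
    response = c("kind", "kappa", "J_ref", "rho", "theta", "n"),
    options = c("t_max", "rtol", "atol", "conv_tol", "blowup_threshold",
                "p_max", "osc_window", "osc_tol", "n_chunks",
                "save_per_chunk", "max_steps"),
    init = c("a", "p", "P"),
    seed = NULL,
    out_dir = NULL
  )
}

#' Load and validate a run configuration
#'
#' Configurations are plain YAML (or JSON) documents with the keys
#' `scenario` (name + constructor arguments) *or* `tissue`/`params`/
#' `variant`/`response`/`init`, plus `options`, `seed` and `out_dir`.
#' Unknown keys, at any level, are rejected with an itemized report;
#' defaults are filled in for everything omitted.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist.", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg A configuration list (as read from file).
#' @export
validate_config <- function(cfg) {
  schema <- config_schema()
  problems <- character()
  unknown_top <- setdiff(names(cfg), names(schema))
  if (length(unknown_top)) {
    problems <- c(problems, sprintf("unknown key(s): %s",
                                    paste(unknown_top, collapse = ", ")))
  }
  for (key in intersect(names(cfg), names(schema))) {
    allowed <- schema[[key]]
    if (!is.null(allowed) && is.list(cfg[[key]])) {
      extra <- setdiff(names(cfg[[key]]), allowed)
      if (length(extra)) {
        problems <- c(problems, sprintf("unknown key(s) under '%s': %s", key,
                                        paste(extra, collapse = ", ")))
      }
    }
  }
  if (is.null(cfg$scenario) && is.null(cfg$tissue)) {
    problems <- c(problems, "either 'scenario' or an inline 'tissue' is required")
  }
  if (!is.null(cfg$scenario)) {
    nm <- cfg$scenario$name %||% cfg$scenario
    if (!nm %in% names(scenario_registry())) {
      problems <- c(problems, sprintf(
        "unknown scenario '%s' (available: %s)", nm,
        paste(names(scenario_registry()), collapse = ", ")))
    }
  }
  if (length(problems)) {
    abort(paste0("invalid configuration:\n", paste("-", problems, collapse = "\n")))
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$variant <- cfg$variant %||% "slow"
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param file Output path (`.yaml` or `.json`).
#' @export
save_config <- function(cfg, file) {
  cfg <- unclass(cfg)
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, file, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(cfg, file)
  }
  invisible(file)
}

# materialize the pieces of a validated config
build_from_config <- function(cfg) {
  if (!is.null(cfg$scenario)) {
    nm <- cfg$scenario$name %||% cfg$scenario
    args <- cfg$scenario$args %||% list()
    args$seed <- cfg$seed
    sc <- do.call(scenario_registry()[[nm]], args)
    if (!is.null(cfg$options)) {
      sc$options <- do.call(integrator_options,
                            utils::modifyList(unclass(sc$options)[
                              names(unclass(sc$options)) != ""],
                              cfg$options))
    }
    return(sc)
  }
  tissue <- tissue_from_json(jsonlite::toJSON(cfg$tissue, digits = NA))
  params <- do.call(model_params, cfg$params)
  response <- do.call(response_function, cfg$response %||% list(kind = "quadratic"))
  opts <- do.call(integrator_options, cfg$options %||% list())
  init <- if (!is.null(cfg$init)) {
    flux_state(tissue, a = cfg$init$a, p = cfg$init$p %||% 0, P = cfg$init$P)
  } else {
    flux_state(tissue, a = ifelse(params$beta_a > 0,
                                  params$alpha_a / pmax(params$beta_a, 1e-300), 0))
  }
  new_scenario("inline", cfg$variant, tissue, params, response,
               function(seed) init, opts, seed = cfg$seed)
}

#' Execute a configuration end to end
#'
#' Builds the scenario, runs the simulation, and (when `out_dir` is set)
#' writes the tidy trajectory CSV, the final state JSON, the report and a
#' reproducibility manifest (config hash, seed, package/R versions).
#'
#' @param cfg A `run_config` (see [load_config()]) or a path to one.
#' @return The report list (invisibly contains the `flux_sim` as
#'   `attr(, "sim")`).
#' @export
run_config <- function(cfg) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  sc <- build_from_config(cfg)
  sim <- run_scenario(sc, seed = cfg$seed)
  rep <- report(sim)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tidy(sim), file.path(cfg$out_dir, "trajectory.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(a = sim$final_state$a, P = sim$final_state$P, p = sim$final_state$p),
      file.path(cfg$out_dir, "final_state.json"), auto_unbox = TRUE,
      digits = NA, null = "null")
    jsonlite::write_json(rep, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    manifest <- list(config_hash = rlang::hash(unclass(cfg)), seed = cfg$seed,
                     package = as.character(utils::packageVersion("fluxcanal")),
                     r_version = R.version.string,
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  attr(rep, "sim") <- sim
  invisible(rep)
}

#' Summarize a run
#'
#' Produces the human-readable/machine-twin summary of a simulation: the
#' termination status, key extrema, and - when the run converged - the
#' orientation topology and (for line tissues with a distinguished first
#' cell) the vein regime.
#'
#' @param sim A `flux_sim`.
#' @return A named list; `as.character()` on it gives the text form, and it
#'   serializes directly to JSON.
#' @export
report <- function(sim) {
  stopifnot(inherits(sim, "flux_sim"))
  out <- list(
    status = sim$status,
    t_end = max(sim$times),
    rhs_norm = sim$rhs_norm,
    max_auxin = max(sim$final_state$a),
    min_auxin = min(sim$final_state$a),
    max_membrane_pin = if (length(sim$final_state$p)) max(sim$final_state$p) else 0
  )
  if (sim$status == "diverged") out$escape_time <- sim$escape_time
  if (sim$status == "oscillating") out$oscillating <- TRUE
  if (sim$status == "converged") {
    orient <- extract_orientation(sim$final_state, sim$tissue)
    topo <- glance(classify_topology(orient))
    out$topology <- as.list(topo)
    chain <- orientation_chain_profile(orient, start = 1L)
    if (!is.null(chain)) {
      bg_beta <- sim$params$beta_a[which.max(sim$params$beta_a == max(sim$params$beta_a))]
      bg <- stats::median(sim$params$alpha_a / pmax(sim$params$beta_a, 1e-300))
      out$regime <- classify_regime(chain, background = bg)$regime
    }
  }
  out
}

# if the orientation restricted to its retained cells is a simple directed
# path starting at `start`, return its auxin profile; else NULL
orientation_chain_profile <- function(orient, start = 1L) {
  ed <- orient$edges
  if (!nrow(ed) || !start %in% ed$from) return(NULL)
  out_deg <- tabulate(ed$from, nbins = orient$n_cells)
  in_deg <- tabulate(ed$to, nbins = orient$n_cells)
  if (any(out_deg > 1) || any(in_deg > 1)) return(NULL)
  path <- start
  cur <- start
  repeat {
    nxt <- ed$to[ed$from == cur]
    if (!length(nxt)) break
    if (nxt %in% path) return(NULL)  # cycle
    path <- c(path, nxt)
    cur <- nxt
  }
  if (length(path) != length(orient$retained)) return(NULL)
  if (is.null(orient$a)) return(NULL)
  orient$a[path]
}
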