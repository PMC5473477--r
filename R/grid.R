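#' Read and validate a simulation-grid configuration
#'
#' Configurations are flat YAML: scenario vectors (`theta_a`, `theta_b`,
#' `n`), `replicates`, `master_seed`, the nominal test level `alpha`, an
#' optional `output_dir`, an `emit_trajectories` flag, and a `designs`
#' list in which each entry names a `design` in
#' `fixed / rpw / dp / rdp / crdp` with its parameters (`u`, `alpha`,
#' `beta` for the urn; `p` for the randomised designs; `ell` or
#' `ell_frac` for the constrained one). See
#' `system.file("extdata", "example_config.yaml", package = "crdp")`.
#'
#' @param path Path to a YAML file.
#' @return A validated config list for [run_grid()].
#' @export
read_run_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run a full design-by-scenario simulation grid
#'
#' Orchestrates the whole evaluation pipeline: for every design and every
#' scenario `(theta_a, theta_b, n)` in the grid, simulate `replicates`
#' trials and reduce them with [summarize_trials()]. Policies for the
#' DP/RDP/CRDP designs are solved once per `(design, n)` and reused
#' across scenarios. Per-run seeds are derived deterministically from
#' `master_seed`, so a rerun with the same config is identical.
#'
#' When `output_dir` is set, writes `metrics.csv` (one row per
#' design-scenario), optionally `trajectories.csv` (per-patient
#' allocation trajectories, long format), and `provenance.yaml` (config
#' echo, seed, package version).
#'
#' @param config A config list or the path to a YAML file
#'   ([read_run_config()]).
#' @param quiet Suppress per-phase progress messages.
#' @return The metrics tibble, invisibly when written to disk.
#' @examples
#' cfg <- list(
#'   designs = list(list(design = "fixed"), list(design = "rpw")),
#'   theta_a = 0.5, theta_b = c(0.3, 0.7), n = 15,
#'   replicates = 50, master_seed = 7
#' )
#' run_grid(cfg, quiet = TRUE)
#' @export
run_grid <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))

  grid <- tidyr::expand_grid(
    design_id = seq_along(config$designs),
    n = config$n, theta_a = config$theta_a, theta_b = config$theta_b
  )
  set.seed(config$master_seed)
  grid$run_seed <- sample.int(.Machine$integer.max, nrow(grid))

  # solve each required policy once per (design, n)
  cache <- new.env(parent = emptyenv())
  design_for <- function(spec, n) {
    key <- paste(spec$design, n,
                 paste(unlist(spec[setdiff(names(spec), "design")]), collapse = "_"),
                 sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    t0 <- proc.time()[["elapsed"]]
    d <- build_design(spec, n)
    if (spec$design %in% c("dp", "rdp", "crdp")) {
      say("solved %s policy for n = %d in %.1fs", spec$design, n,
          proc.time()[["elapsed"]] - t0)
    }
    cache[[key]] <- d
    d
  }

  rows <- vector("list", nrow(grid))
  trajectories <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    spec <- config$designs[[g$design_id]]
    d <- design_for(spec, g$n)
    t0 <- proc.time()[["elapsed"]]
    batch <- simulate_trials(d, g$theta_a, g$theta_b, n = g$n,
                             reps = config$replicates, seed = g$run_seed)
    metrics <- summarize_trials(batch, alpha = config$alpha)
    say("%s  thetaA=%.2f thetaB=%.2f n=%d: %d reps in %.1fs",
        design_label(spec), g$theta_a, g$theta_b, g$n, config$replicates,
        proc.time()[["elapsed"]] - t0)
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(design = design_label(spec),
                     theta_a = g$theta_a, theta_b = g$theta_b, n = g$n,
                     p = d$p %||% NA_real_, ell = d$ell %||% NA_real_),
      metrics
    )
    if (isTRUE(config$emit_trajectories)) {
      trajectories[[i]] <- dplyr::mutate(
        allocation_trajectory(batch),
        design = design_label(spec), theta_a = g$theta_a,
        theta_b = g$theta_b, n = g$n, .before = 1L
      )
    }
  }
  metrics <- dplyr::bind_rows(rows)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(metrics, file.path(config$output_dir, "metrics.csv"))
    if (length(trajectories)) {
      readr::write_csv(dplyr::bind_rows(trajectories),
                       file.path(config$output_dir, "trajectories.csv"))
    }
    yaml::write_yaml(
      list(config = config[setdiff(names(config), "output_dir")],
           package_version = as.character(utils::packageVersion("crdp")),
           timestamp = format(Sys.time(), tz = "UTC")),
      file.path(config$output_dir, "provenance.yaml")
    )
    return(invisible(metrics))
  }
  metrics
}

build_design <- function(spec, n) {
  switch(
    spec$design,
    fixed = fixed_design(),
    rpw = rpw_design(u = spec[["u"]] %||% 1, alpha = spec[["alpha"]] %||% 0,
                     beta = spec[["beta"]] %||% 1),
    dp = dp_design(n = n),
    rdp = rdp_design(n = n, p = spec[["p"]] %||% 0.9),
    crdp = crdp_design(n = n, p = spec[["p"]] %||% 0.9,
                       ell = spec[["ell"]] %||% ((spec[["ell_frac"]] %||% 0.15) * n))
  )
}

design_label <- function(spec) spec$label %||% spec$design

validate_config <- function(config) {
  if (!is.list(config)) rlang::abort("config must be a list.")
  defaults <- list(replicates = 10000L, master_seed = 1L, alpha = 0.1,
                   output_dir = NULL, emit_trajectories = FALSE)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[k] <- defaults[k]
  }
  for (k in c("designs", "theta_a", "theta_b", "n")) {
    if (is.null(config[[k]]) || length(config[[k]]) == 0L) {
      rlang::abort(sprintf("config key `%s` is missing or empty.", k))
    }
  }
  if (any(config$theta_a < 0 | config$theta_a > 1) ||
      any(config$theta_b < 0 | config$theta_b > 1)) {
    rlang::abort("config keys `theta_a`/`theta_b` must lie in [0, 1].")
  }
  if (any(config$n < 1 | config$n != round(config$n))) {
    rlang::abort("config key `n` must hold positive integers.")
  }
  if (config$replicates < 1) rlang::abort("config key `replicates` must be >= 1.")
  known <- c("fixed", "rpw", "dp", "rdp", "crdp")
  for (spec in config$designs) {
    if (is.null(spec$design) || !spec$design %in% known) {
      rlang::abort(sprintf(
        "config key `designs`: each entry needs `design` in {%s}.",
        paste(known, collapse = ", ")
      ))
    }
  }
  config
}

`%||%` <- function(x, y) if (is.null(x)) y else x
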