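## ---------------------------------------------------------------------------
## Plan configuration files (YAML) and the command-line front end
## ---------------------------------------------------------------------------

#' Read a breeding-plan configuration file
#'
#' Structured YAML with a `plan` section (strategy PS/GS/SPB, scale,
#' horizon, burn_in, correlations) and optional `genome`, `founder`,
#' `counts` and `run` sections overriding the shipped wheat-plan defaults.
#' See `inst/examples/plan_b_reduced.yaml` for a template.
#'
#' @param path YAML file.
#' @return list with `plan` (a [wheat_plan()]) and `run` (list with
#'   `replicates`, `seed`, `out`).
#' @export
read_plan_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  p <- cfg$plan
  if (is.null(p$strategy)) stop(sprintf("config %s: plan.strategy missing", path))
  founder <- if (!is.null(cfg$founder))
    do.call(founder_config, cfg$founder)
  plan <- wheat_plan(
    strategy = p$strategy,
    scale = p$scale %||% 1,
    corr_yp_ya = p$corr_yp_ya %||% 0.3,
    corr_bvp = p$corr_bvp %||% 0,
    horizon = p$horizon %||% 25,
    burn_in = p$burn_in %||% 10,
    genome = cfg$genome,
    founder = founder,
    counts = if (!is.null(cfg$counts)) lapply(cfg$counts, as.integer))
  run <- list(replicates = cfg$run$replicates %||% 1,
              seed = cfg$run$seed %||% 1,
              out = cfg$run$out %||% "breedsim_out")
  list(plan = plan, run = run)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
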