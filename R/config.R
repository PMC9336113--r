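#' Read / write a YAML run configuration
#'
#' The configuration file groups the knobs a deployment would tune: the
#' positioning `scenario`, `affected_side`, a `thresholds` block (see
#' [threshold_set()]) and a `coach` block (see [coach_config()]). Absent
#' fields fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return `read_config`: a named list with `scenario`, `affected_side`,
#'   `thresholds` and `coach` entries.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  scenario <- cfg$scenario %||% "S1"
  if (!scenario %in% SCENARIOS) stop("unknown scenario in config: ", scenario)
  th_args <- cfg$thresholds %||% list()
  th <- do.call(threshold_set,
                utils::modifyList(unclass(default_thresholds(scenario)), th_args))
  co <- do.call(coach_config, cfg$coach %||% list())
  list(scenario = scenario,
       affected_side = cfg$affected_side %||% "right",
       thresholds = th, coach = co)
}

#' @rdname read_config
#' @param cfg configuration list as returned by [read_config()].
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(list(scenario = cfg$scenario,
                        affected_side = cfg$affected_side,
                        thresholds = unclass(cfg$thresholds),
                        coach = unclass(cfg$coach)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
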