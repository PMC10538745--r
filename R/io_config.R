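#' Default run configuration for the simulation pipeline
#'
#' One section per stage; every stage reads only its own section. Defaults
#' follow the published tool settings where stated (scaling weights 5/1 on
#' bony landmarks vs upper body, inverse-kinematics error guidelines 2-4 cm
#' maximum / 2 cm RMSE, muscle tracking gains kp=100 kv=20, prosthesis
#' actuator gains kp=1000 kv=90, 1 MN.m prosthesis optimal torque, 1 N.m
#' reserves, 1 ms look-ahead, activation bounds [0.2, 1] in the allocation)
#' and package conventions elsewhere.
#'
#' @param ... named overrides, e.g. \code{mcmc = list(dt = 0.002)} (merged
#'   shallowly per section).
#' @return object of class \code{run_config}.
#' @export
run_config <- function(...) {
  cfg <- list(
    scale = list(bony_weight = 5, upper_weight = 1),
    ik = list(max_marker_error = 0.04, warn_marker_error = 0.02,
              max_rmse = 0.02, tol = 1e-10, max_iter = 60),
    id = list(cutoff_hz = 0),
    rra = list(max_iter = 8, tol = 1e-3),
    mso = list(activation_min = 0, activation_max = 1),
    mcmc = list(kp_muscle = 100, kv_muscle = 20,
                kp_actuator = 1000, kv_actuator = 90,
                lookahead = 0.001, dt = 0.001,
                activation_min = 0.02, activation_max = 1,
                actuator_tau_max = 1e6, reserve_tau_max = 1,
                task_weight = 1, normalized_muscle_cost = FALSE,
                fast_target = FALSE),
    synth = list(cycle = 1.25, stance_fraction = 0.6, speed = 0.7,
                 marker_noise = 0, rate = 100, grf_rate = 1000, cycles = 1),
    events = list(threshold = 20),
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  stopifnot(cfg$ik$max_marker_error > 0, cfg$ik$max_rmse > 0,
            cfg$mcmc$lookahead > 0, cfg$mcmc$dt > 0,
            cfg$mcmc$kp_muscle > 0, cfg$mcmc$kv_muscle > 0,
            cfg$mcmc$kp_actuator > 0, cfg$mcmc$kv_actuator > 0,
            cfg$synth$stance_fraction > 0, cfg$synth$stance_fraction < 1)
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' The file holds per-stage sections mirroring \code{\link{run_config}};
#' missing entries fall back to the defaults.
#'
#' @param path YAML file.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}
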