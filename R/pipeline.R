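# Stage-per-subcommand pipeline mirroring the standard simulation workflow:
# synth -> scale -> ik -> id -> rra -> mso -> mcmc -> analyze. Every stage
# reads its inputs from and writes its outputs to a working directory in
# the standard text formats (TRC/MOT/STO + small JSON summaries), so stages
# can be rerun, inspected or replaced individually. A completed stage is
# skipped on rerun unless forced; all randomness (marker noise) derives
# from the seed in the configuration.

pipeline_stages <- c("synth", "scale", "ik", "id", "rra", "mso", "mcmc",
                     "analyze")

stage_outputs <- function(stage, out_dir) {
  file.path(out_dir, switch(stage,
    synth = c("markers.trc", "grf.mot", "reference_angles.mot", "static.trc"),
    scale = "scale_report.json",
    ik = c("ik_angles.mot", "ik_report.json"),
    id = c("id_torques.sto", "id_residuals.sto", "id_report.json"),
    rra = "rra_report.json",
    mso = c("mso_activations.sto", "mso_actuator_torques.sto", "mso_report.json"),
    mcmc = c("mcmc_angles.mot", "mcmc_activations.sto", "mcmc_report.json"),
    analyze = c("events.json", "energies.json", "group_forces.sto")))
}

pipeline_model <- function(cfg) {
  m <- build_healthy_model()
  apply_amputation(m)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the simulation pipeline
#'
#' Executes the requested stages in order on a synthetic amputee trial.
#' Each stage writes its artifacts into \code{out_dir}; a stage whose
#' outputs already exist is skipped unless \code{force}. With
#' \code{strict = TRUE} a stage whose quality guideline fails (inverse
#' kinematics RMSE, residual guideline) raises an error.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir working directory (created if needed).
#' @param stages subset of \code{c("synth", "scale", "ik", "id", "rra",
#'   "mso", "mcmc", "analyze")}; prerequisites must have run before.
#' @param force rerun stages whose outputs exist.
#' @param strict fail on guideline violations.
#' @return named list of per-stage summaries (invisibly).
#' @export
run_pipeline <- function(config = run_config(), out_dir = "pipeline_out",
                         stages = pipeline_stages, force = FALSE,
                         strict = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  model <- pipeline_model(config)
  summaries <- list()

  need <- function(stage) {
    f <- stage_outputs(stage, out_dir)
    miss <- f[!file.exists(f)]
    if (length(miss))
      stopf("stage '%s' requires missing artifact(s): %s (run that stage first)",
            stage, paste(basename(miss), collapse = ", "))
  }
  done <- function(stage) all(file.exists(stage_outputs(stage, out_dir)))

  for (stage in pipeline_stages) {
    if (!stage %in% stages) next
    if (done(stage) && !force) {
      summaries[[stage]] <- "skipped (outputs exist)"
      next
    }
    summaries[[stage]] <- switch(stage,
      synth = stage_synth(model, config, out_dir),
      scale = stage_scale(model, config, out_dir, strict),
      ik = stage_ik(model, config, out_dir, strict, need),
      id = stage_id(model, config, out_dir, strict, need),
      rra = stage_rra(model, config, out_dir, need),
      mso = stage_mso(model, config, out_dir, need),
      mcmc = stage_mcmc(model, config, out_dir, need),
      analyze = stage_analyze(model, config, out_dir, need))
  }
  invisible(summaries)
}

stage_synth <- function(model, cfg, out_dir) {
  sp <- do.call(gait_spec, c(cfg$synth, list(seed = cfg$seed)))
  trial <- generate_consistent_trial(model, sp)
  write_trc(trial$markers, file.path(out_dir, "markers.trc"))
  write_grf_mot(trial$grf, file.path(out_dir, "grf.mot"))
  ref <- trial$reference
  write_mot(data.frame(time = ref$times, ref$q, check.names = FALSE),
            file.path(out_dir, "reference_angles.mot"), in_degrees = TRUE)
  # short static standing trial for the scale stage
  q0 <- setNames(numeric(length(dynamic_coords(model))), dynamic_coords(model))
  q0["pelvis_ty"] <- 0.93
  fk <- forward_kinematics(model, q0)
  pos <- aperm(array(fk$markers, c(nrow(model$markers), 3L, 3L)), c(3L, 1L, 2L))
  static <- marker_trajectories(model$markers$name, c(0, 0.01, 0.02), pos,
                                sp$rate)
  write_trc(static, file.path(out_dir, "static.trc"))
  list(frames = length(trial$markers$times), cycle = sp$cycle)
}

stage_scale <- function(model, cfg, out_dir, strict) {
  static <- read_trc(file.path(out_dir, "static.trc"))
  sc <- scale_model(model, static,
                    weights = scale_default_weights(model,
                      cfg$scale$bony_weight, cfg$scale$upper_weight))
  rep <- list(factors = as.list(sc$scale_set$factors),
              rmse_m = sc$scale_set$rmse,
              within_guideline = sc$scale_set$within_guideline)
  write_json_report(rep, file.path(out_dir, "scale_report.json"))
  if (strict && !sc$scale_set$within_guideline)
    stopf("scale stage: marker RMSE %.4f m exceeds the 2 cm guideline",
          sc$scale_set$rmse)
  rep
}

stage_ik <- function(model, cfg, out_dir, strict, need) {
  need("synth")
  traj <- read_trc(file.path(out_dir, "markers.trc"))
  ik <- solve_ik_trial(model, traj, settings = cfg$ik)
  write_mot(data.frame(time = ik$trajectory$times, ik$trajectory$q,
                       check.names = FALSE),
            file.path(out_dir, "ik_angles.mot"), in_degrees = TRUE)
  rep <- list(rmse_m = ik$rmse, max_error_m = ik$max_error,
              within_guidelines = ik$within_guidelines,
              n_flagged_frames = length(ik$flagged_frames))
  write_json_report(rep, file.path(out_dir, "ik_report.json"))
  if (strict && !ik$within_guidelines)
    stopf("ik stage: RMSE %.4f m / max %.4f m exceed the guidelines",
          ik$rmse, ik$max_error)
  rep
}

read_angles_mot <- function(path) {
  df <- read_mot(path)
  q <- as.matrix(df[, -1L, drop = FALSE])
  reference_trajectory(df$time, q)
}

stage_id <- function(model, cfg, out_dir, strict, need) {
  need("ik")
  tr <- read_angles_mot(file.path(out_dir, "ik_angles.mot"))
  grf <- as_forceplate_series(read_mot(file.path(out_dir, "grf.mot")))
  id <- inverse_dynamics(model, tr, grf, cutoff = cfg$id$cutoff_hz)
  write_mot(data.frame(time = id$times, id$torques, check.names = FALSE),
            file.path(out_dir, "id_torques.sto"))
  write_mot(data.frame(time = id$times, id$residuals, check.names = FALSE),
            file.path(out_dir, "id_residuals.sto"))
  rep <- id$residual_report
  write_json_report(rep, file.path(out_dir, "id_report.json"))
  if (strict && !rep$within_guideline)
    stopf("id stage: pelvis residuals exceed the 1%% guideline")
  rep
}

stage_rra <- function(model, cfg, out_dir, need) {
  need("id")
  tr <- read_angles_mot(file.path(out_dir, "ik_angles.mot"))
  grf <- as_forceplate_series(read_mot(file.path(out_dir, "grf.mot")))
  rr <- residual_reduction(model, tr, grf, max_iter = cfg$rra$max_iter,
                           tol = cfg$rra$tol)
  rep <- list(mass_change_kg = rr$mass_change,
              torso_com_shift_m = rr$torso_com_shift,
              converged = rr$converged,
              within_guideline = rr$residual_report$within_guideline)
  write_json_report(rep, file.path(out_dir, "rra_report.json"))
  rep
}

stage_mso <- function(model, cfg, out_dir, need) {
  need("id")
  tr <- read_angles_mot(file.path(out_dir, "ik_angles.mot"))
  torq <- read_mot(file.path(out_dir, "id_torques.sto"))
  ms <- run_mso(model, tr, as.matrix(torq[, -1L, drop = FALSE]),
                bounds = cfg$mso)
  write_mot(data.frame(time = ms$times, ms$activations, check.names = FALSE),
            file.path(out_dir, "mso_activations.sto"))
  write_mot(data.frame(time = ms$times, ms$actuator_torques,
                       check.names = FALSE),
            file.path(out_dir, "mso_actuator_torques.sto"))
  rep <- list(n_infeasible_frames = sum(!ms$feasible),
              peak_activation = max(ms$peak_activation),
              mean_activation_step = ms$mean_dactivation)
  write_json_report(rep, file.path(out_dir, "mso_report.json"))
  rep
}

stage_mcmc <- function(model, cfg, out_dir, need) {
  need("synth")
  ref <- read_angles_mot(file.path(out_dir, "reference_angles.mot"))
  grf <- as_forceplate_series(read_mot(file.path(out_dir, "grf.mot")))
  mc <- run_mcmc(model, ref, grf, cfg = cfg$mcmc,
                 t_end = cfg$mcmc$t_end %||% NULL)
  write_mot(data.frame(time = mc$times, mc$q, check.names = FALSE),
            file.path(out_dir, "mcmc_angles.mot"), in_degrees = TRUE)
  write_mot(data.frame(time = mc$times, mc$activations, check.names = FALSE),
            file.path(out_dir, "mcmc_activations.sto"))
  rep <- list(tracking_error_deg = as.list(round(mc$tracking_deg, 6)),
              worst_tracking_deg = max(mc$tracking_deg),
              reserve_ratio = mc$reserve_report$muscle_joint_reserve_ratio,
              peak_actuator_torque = mc$reserve_report$peak_actuator_torque,
              diverged = mc$diverged)
  write_json_report(rep, file.path(out_dir, "mcmc_report.json"))
  rep
}

stage_analyze <- function(model, cfg, out_dir, need) {
  need("id")
  need("mso")
  grf <- as_forceplate_series(read_mot(file.path(out_dir, "grf.mot")))
  ev <- detect_gait_events(grf, threshold = cfg$events$threshold)
  write_json_report(ev, file.path(out_dir, "events.json"))

  tr <- read_angles_mot(file.path(out_dir, "ik_angles.mot"))
  torq <- read_mot(file.path(out_dir, "id_torques.sto"))
  mass <- model_mass(model)
  dyn <- build_dynamic_tree(model)
  trd <- as_reference_trajectory(tr, dyn$coords)
  energies <- list()
  for (cn in c("hip_flexion_l", "hip_flexion_r", "ankle_angle_l")) {
    if (!cn %in% colnames(torq) || !cn %in% dyn$coords) next
    P <- joint_power(torq[[cn]], trd$qd[, cn], mass)
    energies[[paste0(cn, "_J_per_kg")]] <- energy_per_cycle(trd$times, P)
  }
  write_json_report(energies, file.path(out_dir, "energies.json"))

  acts <- read_mot(file.path(out_dir, "mso_activations.sto"),
                   angles_to_rad = FALSE)
  A <- as.matrix(acts[, -1L, drop = FALSE])
  gf <- data.frame(time = trd$times)
  for (g in c("hip_flexors", "hip_extensors", "plantarflexors", "dorsiflexors"))
    for (s in c("r", "l"))
      gf[[paste0(g, "_", s)]] <- muscle_group_force(model, A, tr, g, side = s)
  write_mot(gf, file.path(out_dir, "group_forces.sto"))
  list(events = ev, energies = energies)
}
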