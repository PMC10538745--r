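# Synthetic gait-trial generator. Emulates a treadmill motion-capture
# session: smooth periodic sagittal joint trajectories with gait-like
# phasing (stance ~60%, swing ~40%), marker positions by forward kinematics,
# and ground reactions assigned to the scheduled stance foot by whole-body
# Newton-Euler balance so that the pelvis residuals of inverse dynamics
# vanish by construction. Waveforms are packaged truncated Fourier series;
# the prosthetic-knee variant stays essentially extended (well inside
# 0-5 degrees) through stance and the prosthetic ankle has the limited
# plantarflexion of a passive foot.

#' Specification of a synthetic gait trial
#'
#' @param speed nominal treadmill speed (m/s); metadata only, the belt frame
#'   keeps the pelvis quasi-stationary.
#' @param cycle gait-cycle duration (s).
#' @param stance_fraction stance fraction of the cycle (0 < f < 1).
#' @param marker_noise isotropic marker noise standard deviation (m).
#' @param rate marker sampling rate (Hz).
#' @param grf_rate force-plate sampling rate (Hz).
#' @param cycles number of gait cycles.
#' @param seed RNG seed used for marker noise.
#' @return object of class \code{gait_spec}.
#' @export
gait_spec <- function(speed = 0.7, cycle = 1.25, stance_fraction = 0.6,
                      marker_noise = 0, rate = 100, grf_rate = 1000,
                      cycles = 1L, seed = 1L) {
  stopifnot(stance_fraction > 0, stance_fraction < 1, marker_noise >= 0,
            cycle > 0, rate > 0)
  structure(list(speed = speed, cycle = cycle,
                 stance_fraction = stance_fraction,
                 marker_noise = marker_noise, rate = rate,
                 grf_rate = grf_rate, cycles = as.integer(cycles),
                 seed = as.integer(seed)),
            class = "gait_spec")
}

# map model coordinates to packaged waveforms; value in radians unless the
# waveform name ends in _m. phase = cycle-fraction shift (left leg +0.5).
waveform_map <- function(model) {
  wf <- og_waveforms()
  amput <- model$amputation$spec$side %||% NA_character_
  entry <- function(coord, wave, phase = 0, unit = "deg")
    list(coord = coord, cf = wf[[wave]], phase = phase, unit = unit)
  m <- list(
    entry("pelvis_tx", "pelvis_tx_m", 0, "m"),
    entry("pelvis_ty", "pelvis_ty_m", 0, "m"),
    entry("pelvis_tilt", "pelvis_tilt"),
    entry("lumbar_extension", "lumbar_ext"))
  for (side in c("r", "l")) {
    ph <- if (side == "r") 0 else 0.5
    if (!is.na(amput) && amput == side) {
      m <- c(m, list(
        entry(paste0("hip_flexion_", side), "hip_amp", ph),
        entry("pros_knee", "pros_knee", ph),
        entry("pros_ankle", "pros_ankle", ph)))
    } else {
      ank <- if (!is.na(amput)) "ankle_contra" else "ankle_healthy"
      m <- c(m, list(
        entry(paste0("hip_flexion_", side), "hip_healthy", ph),
        entry(paste0("knee_angle_", side), "knee_healthy", ph),
        entry(paste0("ankle_angle_", side), ank, ph)))
    }
  }
  m
}

#' Generate the reference kinematics of a synthetic trial
#'
#' Evaluates the packaged periodic waveforms (and their analytic first and
#' second derivatives) for every sagittal coordinate of the model at the
#' marker sampling instants. Deterministic: no randomness is involved.
#'
#' @param model an \code{msk_model}.
#' @param spec a \code{\link{gait_spec}}.
#' @param times optional explicit sample times (s); default is the full
#'   trial at \code{spec$rate}.
#' @return a \code{\link{reference_trajectory}} with analytic \code{qd},
#'   \code{qdd}.
#' @export
generate_reference_kinematics <- function(model, spec, times = NULL) {
  if (is.null(times))
    times <- seq(0, spec$cycles * spec$cycle - 1 / spec$rate, by = 1 / spec$rate)
  coords <- dynamic_coords(model)
  wm <- waveform_map(model)
  q <- qd <- qdd <- matrix(0, length(times), length(coords),
                           dimnames = list(NULL, coords))
  for (e in wm) {
    if (!e$coord %in% coords) next
    s <- (times / spec$cycle + e$phase) %% 1
    fac <- if (e$unit == "deg") pi / 180 else 1
    q[, e$coord] <- eval_waveform(e$cf, s, spec$cycle, 0L) * fac
    qd[, e$coord] <- eval_waveform(e$cf, s, spec$cycle, 1L) * fac
    qdd[, e$coord] <- eval_waveform(e$cf, s, spec$cycle, 2L) * fac
  }
  reference_trajectory(times, q, qd, qdd)
}

# load-share of the right-phase foot over the cycle fraction s; the
# double-support transfer is linear, so threshold crossings sit within a
# marker frame of the scheduled heel strikes and toe-offs
stance_weight <- function(s, stance_fraction) {
  ds <- stance_fraction - 0.5  # double-support duration (cycle fraction)
  ramp <- function(x) clamp(x, 0, 1)
  w <- numeric(length(s))
  w <- ifelse(s < ds, ramp(s / ds),
              ifelse(s < 0.5, 1,
                     ifelse(s < 0.5 + ds, 1 - ramp((s - 0.5) / ds), 0)))
  w
}

#' Generate a dynamically consistent synthetic gait trial
#'
#' Markers come from forward kinematics of the reference (plus optional
#' noise). The ground reaction of each instant is the exact net external
#' wrench required by whole-body Newton-Euler balance (computed by inverse
#' dynamics with no external load), split between the two feet by smooth
#' double-support ramps and applied at a centre of pressure under the
#' scheduled stance foot. Inverse dynamics of the generated trial therefore
#' returns pelvis residuals that are numerically zero.
#'
#' @param model an \code{msk_model}.
#' @param spec a \code{\link{gait_spec}}.
#' @param reference optional pre-generated reference trajectory.
#' @return a \code{\link{gait_trial}}.
#' @export
generate_consistent_trial <- function(model, spec = gait_spec(),
                                      reference = NULL) {
  if (is.null(reference)) reference <- generate_reference_kinematics(model, spec)
  dyn <- build_dynamic_tree(model)
  coords <- dyn$coords

  # markers at the camera rate
  nt <- length(reference$times)
  mk <- model$markers
  pos <- array(NA_real_, c(nt, nrow(mk), 3L))
  for (k in seq_len(nt)) {
    fkr <- forward_kinematics(model, reference$q[k, coords], dyn = dyn)
    pos[k, , ] <- fkr$markers
  }
  traj <- marker_trajectories(mk$name, reference$times, pos, spec$rate)
  if (spec$marker_noise > 0)
    traj <- add_marker_noise(traj, spec$marker_noise, spec$seed)

  # ground reactions at the plate rate
  gt <- seq(0, spec$cycles * spec$cycle - 1 / spec$grf_rate,
            by = 1 / spec$grf_rate)
  ref_g <- generate_reference_kinematics(model, spec, times = gt)
  tilt_axis <- -1  # anterior tilt positive corresponds to negative plane rotation
  pel <- match(c("pelvis_tx", "pelvis_ty", "pelvis_tilt"), coords)
  sides <- c("r", "l")
  n_g <- length(gt)
  Fm <- array(0, c(n_g, 2L, 2L))   # frame x side x (Fx, Fy)
  Pm <- array(0, c(n_g, 2L, 2L))   # centre of pressure
  Tm <- matrix(0, n_g, 2L)         # free torque
  for (k in seq_len(n_g)) {
    q <- ref_g$q[k, coords]; qdp <- ref_g$qd[k, coords]; qddp <- ref_g$qdd[k, coords]
    kin <- tree_kinematics(dyn, q, qdp, qddp)
    res <- rnea(dyn, q, qdp, qddp, kin = kin)[pel]
    Ftot <- res[1:2]
    s <- (gt[k] / spec$cycle) %% 1
    wr <- stance_weight(s, spec$stance_fraction)
    w <- c(wr, 1 - wr)
    o <- kin$x[1L, ]  # pelvis origin
    Mtot <- res[3L] / tilt_axis
    for (j in 1:2) {
      seg <- foot_segment(model, sides[j])
      sb <- dyn$seg2body[[seg]]
      fp <- kin$x[sb$body, ] + rot2(kin$phi[sb$body]) %*% (sb$off + c(0.08, -0.06))
      F <- w[j] * Ftot
      # zero-moment-point centre of pressure on the ground line, clamped to
      # the physical foot extent; any remainder becomes a (small) free torque
      px <- if (abs(F[2L]) > 1) {
        o[1L] + (w[j] * Mtot - o[2L] * F[1L]) / F[2L]
      } else fp[1L]
      px <- clamp(px, fp[1L] - 0.11, fp[1L] + 0.10)
      p <- c(px, 0)
      Tz <- w[j] * Mtot - cross2z(p - o, F)
      Fm[k, j, ] <- F; Pm[k, j, ] <- p; Tm[k, j] <- Tz
    }
  }
  plates <- list()
  for (j in 1:2) {
    plates[[sides[j]]] <- list(
      force = cbind(Fm[, j, 1L], Fm[, j, 2L], 0),
      cop = cbind(Pm[, j, 1L], Pm[, j, 2L], 0),
      torque = Tm[, j])
  }
  grf <- forceplate_series(gt, plates, spec$grf_rate)
  gait_trial(traj, grf, reference = reference,
             cycle = list(duration = spec$cycle,
                          stance_fraction = spec$stance_fraction,
                          heel_strikes = list(
                            r = spec$cycle * (seq_len(spec$cycles) - 1L),
                            l = spec$cycle * (seq_len(spec$cycles) - 0.5))))
}

#' Add isotropic Gaussian noise to marker trajectories
#'
#' @param traj a \code{\link{marker_trajectories}}.
#' @param sigma noise standard deviation (m); 0 is the identity.
#' @param seed RNG seed (local to this call; the global RNG state is
#'   restored).
#' @return the noisy \code{marker_trajectories}.
#' @export
add_marker_noise <- function(traj, sigma, seed = 1L) {
  if (sigma == 0) return(traj)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  noise <- array(rnorm(length(traj$positions), 0, sigma), dim(traj$positions))
  traj$positions <- traj$positions + noise
  traj
}
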