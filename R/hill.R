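# Hill-type musculotendon mechanics with a rigid tendon and first-order
# activation dynamics. Curve shapes are package defaults: Gaussian
# active force-length (width 0.45), Hill hyperbola / saturating eccentric
# force-velocity (plateau 1.4), exponential passive toe region starting at
# optimal fiber length.

#' Active force-length multiplier
#'
#' Gaussian bell peaking at 1 when the normalized fiber length is 1:
#' \code{exp(-((l - 1)/w)^2)} with width \code{w = 0.45}.
#'
#' @param l_norm fiber length in units of optimal fiber length (> 0).
#' @param width curve width.
#' @return multiplier in [0, 1].
#' @export
active_force_length <- function(l_norm, width = 0.45) {
  exp(-((l_norm - 1) / width)^2)
}

#' Force-velocity multiplier
#'
#' Concentric branch is the classic rectangular hyperbola
#' \code{(1 + v)/(1 - v/af)} for \code{v} in [-1, 0] (v = -1 is maximal
#' shortening, zero force); the eccentric branch saturates exponentially at
#' 1.4. Monotone non-decreasing and continuous, with \code{f(0) = 1}.
#'
#' @param v_norm fiber velocity in units of maximum contraction velocity
#'   (negative = shortening).
#' @param af concentric shape factor.
#' @param flen eccentric plateau.
#' @return multiplier >= 0.
#' @export
force_velocity <- function(v_norm, af = 0.25, flen = 1.4) {
  v <- v_norm
  conc <- (1 + pmax(v, -1)) / (1 - pmax(v, -1) / af)
  ecc <- flen - (flen - 1) * exp(-v / 0.1)
  ifelse(v <= 0, conc, ecc)
}

#' Passive force-length multiplier
#'
#' Zero at or below optimal fiber length, exponential toe region above it,
#' reaching 1 at a strain of 60\%.
#'
#' @param l_norm normalized fiber length.
#' @param k_shape exponential shape factor.
#' @param strain_one strain at which the passive force equals the maximum
#'   isometric force.
#' @return multiplier >= 0.
#' @export
passive_force_length <- function(l_norm, k_shape = 5, strain_one = 0.6) {
  e <- pmax(l_norm - 1, 0)
  (exp(k_shape * e) - 1) / (exp(k_shape * strain_one) - 1)
}

#' Musculotendon fiber force
#'
#' Rigid-tendon Hill force \code{F0 * (a * fl(l) * fv(v) + fp(l))}, linear in
#' the activation at fixed kinematics (the linearity the per-frame
#' redundancy solvers exploit). Disabled-anchored and removed units produce
#' zero force regardless of state.
#'
#' @param F0 maximum isometric force (N).
#' @param a activation in [0, 1].
#' @param l_norm,v_norm normalized fiber length and velocity.
#' @param status unit status; only \code{"active"} produces force.
#' @return force in N (>= 0).
#' @export
fiber_force <- function(F0, a, l_norm, v_norm = 0, status = "active") {
  out <- F0 * (a * active_force_length(l_norm) * force_velocity(v_norm) +
                 passive_force_length(l_norm))
  out[status != "active"] <- 0
  pmax(out, 0)
}

#' One step of first-order activation dynamics
#'
#' Exact exponential update of the bilinear first-order lag between neural
#' excitation and activation: time constant 10 ms when the excitation exceeds
#' the activation (activation) and 40 ms otherwise (deactivation). The update
#' is a contraction and keeps the activation in [0, 1] for excitations in
#' [0, 1].
#'
#' @param a current activation (vector ok).
#' @param u excitation in [0, 1].
#' @param dt time step (s).
#' @param tau_act,tau_deact rise and fall time constants (s).
#' @return the activation after \code{dt}.
#' @export
activation_step <- function(a, u, dt, tau_act = 0.010, tau_deact = 0.040) {
  tau <- ifelse(u > a, tau_act, tau_deact)
  u + (a - u) * exp(-dt / tau)
}

# ---- musculotendon kinematics from model coordinates ----------------------

# moment-arm matrix (n_muscles x n_dyn_coords) for the sagittal coordinates;
# constant arms mapped by side: r_hip -> hip_flexion_<side>, r_knee ->
# knee_angle_<side> or pros-side zero (anchored units already zeroed),
# r_ankle -> ankle_angle_<side>, r_lumbar -> lumbar_extension
muscle_arm_matrix <- function(model, coords = dynamic_coords(model)) {
  mus <- model$muscles
  n <- nrow(mus)
  R <- matrix(0, n, length(coords), dimnames = list(mus$name, coords))
  for (side in c("r", "l")) {
    sel <- mus$side == side
    hip <- paste0("hip_flexion_", side)
    knee <- paste0("knee_angle_", side)
    ankle <- paste0("ankle_angle_", side)
    if (!is.null(model$amputation) && model$amputation$spec$side == side) {
      knee <- "pros_knee"; ankle <- "pros_ankle"
    }
    if (hip %in% coords) R[sel, hip] <- mus$r_hip[sel]
    if (knee %in% coords) R[sel, knee] <- mus$r_knee[sel]
    if (ankle %in% coords) R[sel, ankle] <- mus$r_ankle[sel]
    if ("lumbar_extension" %in% coords)
      R[sel, "lumbar_extension"] <- mus$r_lumbar[sel]
  }
  R
}

# mid-gait reference posture at which every fiber sits at optimal length
# (rad); anchoring the operating point mid-range keeps the force-length
# multiplier useful over the whole motion, as tendon slack tuning does in
# full musculotendon models
muscle_reference_posture <- function(coords) {
  q <- setNames(numeric(length(coords)), coords)
  q[grepl("^hip_flexion", coords)] <- 0.26
  q[coords %in% c("knee_angle_r", "knee_angle_l", "pros_knee")] <- 0.44
  q[coords %in% c("ankle_angle_r", "ankle_angle_l", "pros_ankle")] <- -0.09
  q
}

# normalized fiber lengths and velocities under the rigid-tendon model:
# l_mt = lopt + lslack - R (q - q_ref)  =>  l_norm = 1 - R (q - q_ref)/lopt,
# v_norm = -(R qd)/(lopt * vmax)
muscle_fiber_state <- function(model, q, qd = NULL,
                               R = muscle_arm_matrix(model)) {
  mus <- model$muscles
  qr_ <- muscle_reference_posture(colnames(R))
  dl <- as.numeric(R %*% (q - qr_))
  l_norm <- 1 - dl / mus$lopt
  v_norm <- if (is.null(qd)) rep(0, nrow(mus)) else
    -as.numeric(R %*% qd) / (mus$lopt * mus$vmax)
  list(l_norm = pmax(l_norm, 0.01), v_norm = clamp(v_norm, -1, 10))
}
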