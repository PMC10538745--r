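# Modified Computed Muscle Control (mCMC): a proportional-derivative
# look-ahead tracking law on every sagittal coordinate,
#     qdd_des(t+T) = qdd_exp(t+T) + kv [qd_exp(t) - qd(t)] + kp [q_exp(t) - q(t)],
# followed at each step by a control allocation over all effectors that
# minimizes
#     J = sum_i (a_i / F0_i)^2 + sum_j (x_j / tau_max_j)^2
#         + sum_k w_k (qdd_des_k - qdd_k)^2 ,
# with muscle activations in [0.2, 1], reserve controls in [0, 1] and
# prosthesis-actuator controls in [-1, 1]. The prosthesis actuators carry a
# 1 MN.m optimal torque (nearly free in J); reserves carry the default
# 1 N.m (heavily penalized), so the allocation recruits muscles and the
# prosthesis and leaves reserves as a diagnostic. Muscles follow their
# first-order activation dynamics inside the forward simulation while the
# ideal actuators respond instantaneously.

#' Per-coordinate tracking gains
#'
#' Muscle-driven coordinates use the muscle gains (defaults kp=100, kv=20);
#' coordinates actuated only by the prosthesis use the actuator gains
#' (defaults kp=1000, kv=90).
#'
#' @param model an \code{msk_model}.
#' @param cfg the \code{mcmc} section of a \code{\link{run_config}}.
#' @return list with vectors \code{kp}, \code{kv} over the dynamic
#'   coordinates.
#' @export
tracking_gains <- function(model, cfg = run_config()$mcmc) {
  coords <- dynamic_coords(model)
  kp <- setNames(rep(cfg$kp_muscle, length(coords)), coords)
  kv <- setNames(rep(cfg$kv_muscle, length(coords)), coords)
  if (!is.null(model$actuators)) {
    pc <- intersect(model$actuators$coord, coords)
    kp[pc] <- cfg$kp_actuator
    kv[pc] <- cfg$kv_actuator
  }
  list(kp = kp, kv = kv)
}

# cubic-spline interpolators for a reference trajectory (value, qd, qdd)
ref_interpolator <- function(reference, coords) {
  tr <- as_reference_trajectory(reference, coords)
  mk <- function(mat) lapply(seq_along(coords), function(j)
    splinefun(tr$times, mat[, j], method = "natural"))
  fq <- mk(tr$q); fqd <- mk(tr$qd); fqdd <- mk(tr$qdd)
  function(t, what = "q") {
    f <- switch(what, q = fq, qd = fqd, qdd = fqdd)
    setNames(vapply(f, function(g) g(t), 0), coords)
  }
}

#' Desired accelerations of the tracking law
#'
#' Evaluates the look-ahead PD law componentwise with the class-specific
#' gains of each coordinate. With zero tracking error this returns the
#' experimental acceleration at \code{t + T}.
#'
#' @param ref function from \code{ref_interpolator}, or a
#'   \code{reference_trajectory} (interpolated on the fly).
#' @param state list with current \code{q}, \code{qd} (dyn order).
#' @param gains list with \code{kp}, \code{kv} vectors.
#' @param t current time (s).
#' @param lookahead look-ahead T (s).
#' @param coords coordinate names (needed when \code{ref} is a trajectory).
#' @return named vector of desired accelerations.
#' @export
desired_accelerations <- function(ref, state, gains, t, lookahead = 0.001,
                                  coords = names(gains$kp)) {
  if (inherits(ref, "reference_trajectory")) ref <- ref_interpolator(ref, coords)
  qdd_exp <- ref(t + lookahead, "qdd")
  q_exp <- ref(t, "q"); qd_exp <- ref(t, "qd")
  qdd_exp + gains$kv * (qd_exp - state$qd) + gains$kp * (q_exp - state$q)
}

# assemble the affine controls -> accelerations map and the cost pieces at
# the current state; reused by allocate_controls and the simulation loop.
# When the current activations `a` and the step `dt` are given, muscle
# decision variables are neural excitations and their torque authority is
# the exact one-step response of the first-order activation dynamics
# (a_+ = a e^{-dt/tau} + u (1 - e^{-dt/tau})); `tau_branch` selects the
# rise/fall time constant per muscle.
mcmc_allocation_problem <- function(model, dyn, q, qd, grf = NULL, t = 0,
                                    cfg = run_config()$mcmc,
                                    Rarm = NULL, a = NULL, dt = NULL,
                                    tau_branch = NULL, cache = NULL) {
  mus <- model$muscles
  if (is.null(Rarm)) Rarm <- muscle_arm_matrix(model, dyn$coords)
  fs <- muscle_fiber_state(model, q, qd, R = Rarm)
  gain <- fiber_force(mus$F0, 1, fs$l_norm, fs$v_norm, mus$status) -
    fiber_force(mus$F0, 0, fs$l_norm, fs$v_norm, mus$status)
  passive <- fiber_force(mus$F0, 0, fs$l_norm, 0, mus$status)
  nmus <- nrow(mus)
  gain_eff <- gain
  force_base <- passive
  if (!is.null(a) && !is.null(dt)) {
    if (is.null(tau_branch)) tau_branch <- rep(0.010, nmus)
    decay <- exp(-dt / tau_branch)
    force_base <- passive + gain * a * decay  # force carried by decaying activation
    gain_eff <- gain * (1 - decay)            # one-step authority of the excitation
  }
  coords <- dyn$coords
  nq <- length(coords)

  act <- model$actuators
  nact <- if (is.null(act)) 0L else nrow(act)
  res_coords <- coords
  nres <- length(res_coords)

  # torque map B (nq x n_eff)
  B <- matrix(0, nq, nmus + nact + nres)
  B[, seq_len(nmus)] <- t(Rarm * gain_eff)
  if (nact) for (i in seq_len(nact)) {
    j <- match(act$coord[i], coords)
    if (!is.na(j)) B[j, nmus + i] <- act$tau_max[i]
  }
  for (i in seq_len(nres)) B[match(res_coords[i], coords), nmus + nact + i] <-
    cfg$reserve_tau_max
  tau_pass <- as.numeric(t(Rarm) %*% force_base)

  if (is.null(cache)) {
    M <- mass_matrix(dyn, q)
    bias <- rnea(dyn, q, qd, numeric(nq))
    ext <- if (is.null(grf)) NULL else grf_wrenches(model, dyn, grf, t)
    Q <- ext_generalized(dyn, q, ext)
  } else {
    M <- cache$M; bias <- cache$bias; Q <- cache$Q
  }
  qdd0 <- solve(M, tau_pass + Q - bias)
  G <- solve(M, B)

  d_cost <- c(if (cfg$normalized_muscle_cost) rep(1, nmus) else 1 / mus$F0^2,
              if (nact) 1 / act$tau_max^2 else numeric(0),
              rep(1 / cfg$reserve_tau_max^2, nres))
  lb <- c(rep(cfg$activation_min, nmus), rep(-1, nact), rep(0, nres))
  ub <- c(rep(cfg$activation_max, nmus), rep(1, nact), rep(1, nres))
  list(G = G, qdd0 = qdd0, d = d_cost, lb = lb, ub = ub, B = B,
       tau_pass = tau_pass, M = M, bias = bias, Q = Q,
       gain = gain, passive = passive,
       n_muscles = nmus, n_actuators = nact, n_reserves = nres,
       coords = coords,
       effectors = c(mus$name, if (nact) act$name,
                     paste0("reserve_", res_coords)))
}

#' Allocate controls to realize desired accelerations
#'
#' Solves the strictly convex allocation quadratic program at the current
#' state: effort (muscles by 1/F0^2, actuators and reserves by 1/tau_max^2)
#' plus weighted squared acceleration mismatch, over the affine
#' controls-to-accelerations map of the rigid-tendon model. In fast-target
#' mode the acceleration match is a hard equality (falling back to the
#' penalty form if the demand is unattainable within the bounds).
#'
#' @param problem an allocation problem from the internal builder (state,
#'   dynamics and cost pieces); tests may construct one directly to use toy
#'   plants.
#' @param qdd_des desired accelerations (dyn order).
#' @param weights per-coordinate task weights w_k (scalar or vector >= 0;
#'   they must not all be zero).
#' @param fast_target logical: enforce the acceleration match exactly.
#' @return a \code{control_solution} with fields \code{x} (all controls),
#'   \code{activations}, \code{actuator_controls}, \code{reserve_controls},
#'   \code{qdd} (realized), \code{J}, \code{J_effort}, \code{J_track},
#'   \code{feasible}.
#' @export
allocate_controls <- function(problem, qdd_des, weights = 1,
                              fast_target = FALSE) {
  p <- problem
  n <- length(p$d)
  w <- rep_len(weights, length(p$qdd0))
  if (all(w == 0)) stopf("all acceleration-tracking weights are zero")
  e <- qdd_des - p$qdd0
  feasible <- TRUE
  if (fast_target) {
    H <- diag(2 * p$d, n)
    ans <- solve_boxqp(H, numeric(n), p$lb, p$ub, Aeq = p$G, beq = e)
    if (ans$status != "optimal") {
      feasible <- FALSE
    } else {
      u <- ans$x
    }
  }
  if (!fast_target || !feasible) {
    Gw <- p$G * sqrt(w)
    H <- diag(2 * p$d, n) + 2 * crossprod(Gw)
    cc <- -2 * as.numeric(crossprod(Gw, sqrt(w) * e))
    ans <- solve_boxqp(H, cc, p$lb, p$ub)
    u <- ans$x
    feasible <- feasible && ans$status == "optimal"
  }
  qdd <- p$qdd0 + as.numeric(p$G %*% u)
  nm <- p$n_muscles; na <- p$n_actuators
  J_eff <- sum(p$d * u^2)
  J_trk <- sum(w * (qdd_des - qdd)^2)
  u <- setNames(u, p$effectors)
  structure(list(
    x = u,
    activations = u[seq_len(nm)],
    actuator_controls = if (na) u[nm + seq_len(na)] else numeric(0),
    reserve_controls = u[(nm + na + 1L):n],
    qdd = setNames(qdd, p$coords),
    J = J_eff + J_trk, J_effort = J_eff, J_track = J_trk,
    feasible = feasible), class = "control_solution")
}

#' Forward simulation under modified Computed Muscle Control
#'
#' Steps the model forward with the PD look-ahead law and per-step control
#' allocation: at each step the desired accelerations are computed from the
#' reference, controls are allocated, muscle activations advance through
#' their first-order dynamics (the allocated activation acts as the neural
#' excitation), actuator torques apply instantaneously, and the state
#' integrates semi-implicitly under the recorded ground reactions.
#'
#' @param model an \code{msk_model}.
#' @param reference a \code{reference_trajectory} spanning the simulation
#'   window.
#' @param grf a \code{forceplate_series} (or NULL for free dynamics).
#' @param cfg the \code{mcmc} section of a \code{\link{run_config}}.
#' @param t_end simulation end time (default: reference end).
#' @param weights per-coordinate task weights.
#' @return list with \code{times}, \code{q}, \code{qd} (state series),
#'   \code{activations}, \code{actuator_torques}, \code{reserve_torques},
#'   \code{tracking} (per-coordinate mean absolute error, rad),
#'   \code{reserve_report} (peak reserve vs peak prosthesis torque),
#'   \code{diverged}.
#' @export
run_mcmc <- function(model, reference, grf = NULL, cfg = run_config()$mcmc,
                     t_end = NULL, weights = NULL) {
  dyn <- build_dynamic_tree(model)
  coords <- dyn$coords
  Rarm <- muscle_arm_matrix(model, coords)
  ref <- ref_interpolator(reference, coords)
  gains <- tracking_gains(model, cfg)
  w <- if (is.null(weights)) rep(cfg$task_weight, length(coords)) else
    rep_len(weights, length(coords))

  t0 <- min(reference$times)
  if (is.null(t_end)) t_end <- max(reference$times)
  if (!is.null(grf)) t_end <- min(t_end, max(grf$times))
  times <- seq(t0, t_end, by = cfg$dt)
  nt <- length(times)

  nmus <- nrow(model$muscles)
  q <- ref(t0, "q"); qd <- ref(t0, "qd")
  # initialize activations from a static-optimization solve of the first
  # frame so the simulation does not start with a force deficit
  a <- rep(cfg$activation_min, nmus)
  ext0 <- if (is.null(grf)) NULL else grf_wrenches(model, dyn, grf, t0)
  tau0 <- rnea(dyn, q, qd, ref(t0, "qdd"), ext = ext0)
  ws <- tryCatch(
    solve_mso_frame(mso_problem(model, q, qd, setNames(tau0, coords))),
    error = function(e) NULL)
  if (!is.null(ws)) a <- clamp(ws$activations,
                               cfg$activation_min, cfg$activation_max)

  Qs <- matrix(NA_real_, nt, length(coords), dimnames = list(NULL, coords))
  Qds <- Qs
  As <- matrix(NA_real_, nt, nmus, dimnames = list(NULL, model$muscles$name))
  nact <- if (is.null(model$actuators)) 0L else nrow(model$actuators)
  Ta <- matrix(NA_real_, nt, nact,
               dimnames = list(NULL, model$actuators$name))
  Tr <- matrix(NA_real_, nt, length(coords),
               dimnames = list(NULL, paste0("reserve_", coords)))
  err <- matrix(NA_real_, nt, length(coords), dimnames = list(NULL, coords))
  Jtrk <- numeric(nt); passes <- integer(nt); feas <- logical(nt)
  diverged <- FALSE

  for (k in seq_len(nt)) {
    t <- times[k]
    Qs[k, ] <- q; Qds[k, ] <- qd
    err[k, ] <- q - ref(t, "q")
    if (any(!is.finite(q)) || max(abs(err[k, ])) > 1) {
      diverged <- TRUE
      break
    }
    qdd_des <- desired_accelerations(ref, list(q = q, qd = qd), gains, t,
                                     lookahead = cfg$lookahead, coords = coords)
    # the rise/fall branch of each muscle's one-step activation response
    # depends on the excitation itself: iterate to a fixed point, holding
    # flip-flopping muscles at their current activation (branch-neutral)
    tb <- rep(0.010, nmus)
    cache <- NULL
    lb_fix <- NULL
    prev_tb <- NULL
    for (pass in 1:6) {
      p <- mcmc_allocation_problem(model, dyn, q, qd, grf, t, cfg,
                                   Rarm = Rarm, a = a, dt = cfg$dt,
                                   tau_branch = tb, cache = cache)
      cache <- list(M = p$M, bias = p$bias, Q = p$Q)
      if (!is.null(lb_fix)) { p$lb[lb_fix] <- a[lb_fix]; p$ub[lb_fix] <- a[lb_fix] }
      sol <- allocate_controls(p, qdd_des, weights = w,
                               fast_target = cfg$fast_target)
      u <- clamp(sol$activations, 0, 1)
      tbn <- ifelse(u > a, 0.010, 0.040)
      if (identical(tbn, tb)) break
      if (pass == 5L) {
        # genuine two-cycles: hold at the current activation (branch-neutral)
        lb_fix <- which(tbn != tb & (is.null(prev_tb) | tbn == prev_tb))
        if (!length(lb_fix)) lb_fix <- which(tbn != tb)
        tbn[lb_fix] <- 0.040
      }
      prev_tb <- tb
      tb <- tbn
    }
    Jtrk[k] <- sol$J_track; passes[k] <- pass; feas[k] <- sol$feasible
    # muscles obey activation dynamics; actuators are instantaneous
    a <- clamp(activation_step(a, u, cfg$dt), 0, 1)
    tau <- as.numeric(t(Rarm) %*% (p$gain * a + p$passive))
    tau_act <- numeric(length(coords))
    if (nact) {
      torq <- sol$actuator_controls * model$actuators$tau_max
      for (i in seq_len(nact)) {
        j <- match(model$actuators$coord[i], coords)
        tau_act[j] <- tau_act[j] + torq[i]
      }
      Ta[k, ] <- torq
    }
    tau_res <- sol$reserve_controls * cfg$reserve_tau_max
    Tr[k, ] <- tau_res
    As[k, ] <- a
    qdd <- solve(p$M, tau + tau_act + tau_res + p$Q - p$bias)
    qd <- qd + cfg$dt * qdd
    q <- q + cfg$dt * qd
  }

  ok <- seq_len(if (diverged) k else nt)
  track <- colMeans(abs(err[ok, , drop = FALSE]), na.rm = TRUE)
  peak_res <- apply(abs(Tr[ok, , drop = FALSE]), 2L, max)
  peak_act <- if (nact) max(abs(Ta[ok, , drop = FALSE])) else NA_real_
  muscle_coords <- setdiff(coords, c(model$actuators$coord,
                                     "pelvis_tx", "pelvis_ty", "pelvis_tilt"))
  reserve_report <- list(
    peak_reserve = peak_res,
    peak_actuator_torque = peak_act,
    muscle_joint_reserve_ratio =
      if (nact && is.finite(peak_act) && peak_act > 0)
        max(peak_res[paste0("reserve_", muscle_coords)]) / peak_act
      else NA_real_)
  list(times = times[ok], q = Qs[ok, , drop = FALSE],
       qd = Qds[ok, , drop = FALSE],
       activations = As[ok, , drop = FALSE],
       actuator_torques = Ta[ok, , drop = FALSE],
       reserve_torques = Tr[ok, , drop = FALSE],
       tracking = track, tracking_deg = rad2deg(track),
       reserve_report = reserve_report,
       J_track = Jtrk[ok], allocation_passes = passes[ok],
       allocation_feasible = feas[ok],
       diverged = diverged,
       last_state = list(q = q, qd = qd, t = times[min(k, nt)]))
}
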