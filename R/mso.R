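# Modified Static Optimization (mSO): per-frame resolution of the muscle
# redundancy including the two ideal prosthesis actuators. At each frame the
# net joint torques from inverse dynamics must be reproduced by the active
# muscle fiber forces times their moment arms plus the actuator torques,
#     sum_m [ a_m f(F0_m, l_m, v_m) ] r_mj + sum_act a_act tau_max = tau_j ,
# while minimizing  J = sum_m a_m^2 + sum_act a_act^2  (actuator activations
# are normalized controls, torque / tau_max, so both sums are
# dimensionless). This is a strictly convex equality + box constrained
# quadratic program with a unique solution.

#' Assemble the per-frame mSO problem
#'
#' Builds the capacity matrix mapping effector controls (muscle activations,
#' actuator normalized controls) to generalized torques at the actuated
#' sagittal coordinates, the passive-force torque offset, and the bounds.
#' The pelvis coordinates are excluded: their generalized forces are the
#' residuals, not a demand on muscles.
#'
#' @param model an \code{msk_model}.
#' @param q,qd coordinate positions/velocities (dyn order).
#' @param tau named torque demand over the dynamic coordinates.
#' @param bounds list with \code{activation_min}, \code{activation_max}.
#' @return an \code{mso_problem}: list with \code{R} (coords x effectors),
#'   \code{tau} (demand minus passive offset), \code{lb}, \code{ub},
#'   \code{effectors}, \code{coords}.
#' @export
mso_problem <- function(model, q, qd, tau, bounds = list()) {
  dyn <- build_dynamic_tree(model)
  coords <- setdiff(dyn$coords, c("pelvis_tx", "pelvis_ty", "pelvis_tilt"))
  mus <- model$muscles
  Rarm <- muscle_arm_matrix(model, dyn$coords)[, coords, drop = FALSE]
  fs <- muscle_fiber_state(model, order_q(dyn, q), order_q(dyn, qd),
                           R = muscle_arm_matrix(model, dyn$coords))
  gain <- fiber_force(mus$F0, 1, fs$l_norm, fs$v_norm, mus$status) -
    fiber_force(mus$F0, 0, fs$l_norm, fs$v_norm, mus$status)
  passive <- fiber_force(mus$F0, 0, fs$l_norm, 0, mus$status)
  # capacity of a unit activation; passive force contributes a fixed torque
  A_mus <- Rarm * gain
  tau_off <- as.numeric(t(Rarm) %*% passive)
  names(tau_off) <- coords

  act <- model$actuators
  A_act <- NULL
  if (!is.null(act)) {
    A_act <- matrix(0, length(coords), nrow(act),
                    dimnames = list(coords, act$name))
    for (i in seq_len(nrow(act)))
      if (act$coord[i] %in% coords) A_act[act$coord[i], i] <- act$tau_max[i]
  }
  Rcap <- t(A_mus)                       # coords x muscles
  if (!is.null(A_act)) Rcap <- cbind(Rcap, A_act)
  effectors <- c(mus$name, if (!is.null(act)) act$name)
  lb <- c(rep(bounds$activation_min %||% 0, nrow(mus)),
          rep(-1, if (is.null(act)) 0 else nrow(act)))
  ub <- c(rep(bounds$activation_max %||% 1, nrow(mus)),
          rep(1, if (is.null(act)) 0 else nrow(act)))
  tau <- tau[coords]
  structure(list(R = Rcap, tau = as.numeric(tau) - tau_off, lb = lb, ub = ub,
                 effectors = effectors, n_muscles = nrow(mus),
                 coords = coords),
            class = "mso_problem")
}

#' Solve one frame of modified Static Optimization
#'
#' Minimizes the sum of squared muscle activations plus squared actuator
#' controls subject to the torque-balance equalities and the bounds.
#' Coordinates with no effector and negligible demand are dropped; a
#' coordinate with demand but no capacity, or a demand outside the feasible
#' set, yields a flagged least-squares solution with the violation reported
#' (never silent clipping).
#'
#' @param problem an \code{mso_problem} (or the pieces: a capacity matrix
#'   \code{R}, demand \code{tau}, bounds \code{lb}, \code{ub}).
#' @return a \code{control_solution}: list with \code{x} (all effector
#'   controls), \code{activations}, \code{actuator_controls},
#'   \code{torques} (realized per coordinate), \code{J} (objective),
#'   \code{feasible}, \code{violation}.
#' @export
solve_mso_frame <- function(problem) {
  R <- problem$R; tau <- problem$tau
  n <- ncol(R)
  lb <- problem$lb; ub <- problem$ub
  H <- diag(2, n)
  cc <- numeric(n)

  cap <- rowSums(abs(R)) > 1e-12
  dead <- which(!cap & abs(tau) > 1e-9)
  keep <- which(cap)
  ans <- solve_boxqp(H, cc, lb, ub,
                     Aeq = R[keep, , drop = FALSE], beq = tau[keep])
  feasible <- ans$status == "optimal" && length(dead) == 0L
  violation <- max(ans$eq_residual, if (length(dead)) max(abs(tau[dead])) else 0)
  x <- ans$x
  nm <- problem$n_muscles
  real <- as.numeric(R %*% x)
  names(real) <- problem$coords
  structure(list(x = setNames(x, problem$effectors),
                 activations = x[seq_len(nm)],
                 actuator_controls = if (n > nm) x[(nm + 1L):n] else numeric(0),
                 torques = real, J = sum(x^2),
                 feasible = feasible, violation = violation),
            class = "control_solution")
}

#' Run modified Static Optimization over a trial
#'
#' Frame loop over the inverse-dynamics torques: builds and solves the
#' per-frame problem, collecting activations, actuator torques and
#' feasibility flags.
#'
#' @param model an \code{msk_model}.
#' @param trajectory a \code{reference_trajectory}.
#' @param torques matrix (frames x coords) from \code{\link{inverse_dynamics}}.
#' @param bounds activation bounds (see \code{\link{mso_problem}}).
#' @return list with \code{activations} (frames x muscles),
#'   \code{actuator_torques} (frames x actuators), \code{J} (per frame),
#'   \code{feasible} (per frame), \code{times}, and summary
#'   \code{peak_activation}, \code{mean_dactivation} (mean frame-to-frame
#'   absolute activation change).
#' @export
run_mso <- function(model, trajectory, torques, bounds = list()) {
  dyn <- build_dynamic_tree(model)
  tr <- as_reference_trajectory(trajectory, dyn$coords)
  nt <- length(tr$times)
  mus <- model$muscles
  act <- model$actuators
  A <- matrix(0, nt, nrow(mus), dimnames = list(NULL, mus$name))
  Tq <- matrix(0, nt, if (is.null(act)) 0 else nrow(act),
               dimnames = list(NULL, act$name))
  J <- numeric(nt); feas <- logical(nt)
  for (k in seq_len(nt)) {
    pb <- mso_problem(model, tr$q[k, ], tr$qd[k, ],
                      setNames(torques[k, dyn$coords], dyn$coords), bounds)
    sol <- solve_mso_frame(pb)
    A[k, ] <- sol$activations
    if (ncol(Tq)) Tq[k, ] <- sol$actuator_controls * act$tau_max
    J[k] <- sol$J; feas[k] <- sol$feasible
  }
  list(activations = A, actuator_torques = Tq, J = J, feasible = feas,
       times = tr$times,
       peak_activation = apply(A, 2L, max),
       mean_dactivation = if (nt > 1L) mean(abs(diff(A))) else 0)
}
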