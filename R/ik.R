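# Inverse kinematics: per-frame weighted least-squares fit of the sagittal
# model coordinates to experimental marker positions, damped Gauss-Newton
# with warm starts from the previous frame. The optimized residual is the
# in-plane (x, y) marker error; reported errors are full 3-D distances.

#' Default per-marker inverse-kinematics weights
#'
#' Segment-identifying markers (thigh/tibia wands, heel, toe) are weighted
#' above the bony landmarks, the reverse of the scaling weights.
#'
#' @param model an \code{msk_model}.
#' @param segment_weight,landmark_weight the two weight levels.
#' @return named numeric vector over the model's markers.
#' @export
ik_default_weights <- function(model, segment_weight = 5, landmark_weight = 1) {
  nm <- model$markers$name
  w <- rep(landmark_weight, length(nm))
  names(w) <- nm
  seg_markers <- nm[grepl("(THI|TIB|HEE|TOE)$", nm)]
  w[seg_markers] <- segment_weight
  w
}

#' Solve inverse kinematics for one frame
#'
#' Minimizes \code{sum_i w_i ||m_i_exp - m_i_virtual(q)||^2} over the
#' unlocked sagittal coordinates by damped Gauss-Newton with analytic marker
#' Jacobians. Deterministic given the initial guess. Markers flagged missing
#' are excluded; a frame whose visible markers do not constrain all
#' coordinates (rank-deficient Jacobian) is flagged and the initial guess is
#' returned unchanged.
#'
#' @param model an \code{msk_model}.
#' @param markers matrix (n_markers x 3) of world positions in metres,
#'   rownames = marker names; NA rows are treated as missing.
#' @param weights named weights (default \code{\link{ik_default_weights}}).
#' @param q0 initial guess (default neutral pose).
#' @param settings list with \code{tol}, \code{max_iter}.
#' @param dyn optional pre-built tree.
#' @return list with \code{q} (named), \code{errors} (per-marker 3-D
#'   distances), \code{rmse}, \code{max_error}, \code{objective},
#'   \code{flagged} (under-constrained), \code{iterations}.
#' @export
solve_ik_frame <- function(model, markers, weights = NULL, q0 = NULL,
                           settings = list(), dyn = NULL) {
  if (is.null(dyn)) dyn <- build_dynamic_tree(model)
  tol <- settings$tol %||% 1e-10
  max_iter <- settings$max_iter %||% 60L
  if (is.null(weights)) weights <- ik_default_weights(model)
  if (any(weights <= 0)) stopf("marker weights must be > 0")
  n <- dyn$n
  q <- if (is.null(q0)) numeric(n) else order_q(dyn, q0)

  mk <- model$markers
  use <- mk$name[mk$name %in% rownames(markers)]
  obs <- markers[use, , drop = FALSE]
  vis <- use[apply(is.finite(obs[, 1:2, drop = FALSE]), 1L, all)]
  obs <- markers[vis, , drop = FALSE]
  w <- weights[vis]
  mrow <- match(vis, mk$name)

  objective <- function(pred2) sum(w * rowSums((obs[, 1:2, drop = FALSE] - pred2)^2))

  predict2 <- function(q) {
    kin <- tree_kinematics(dyn, q)
    P <- matrix(0, length(vis), 2L)
    for (ii in seq_along(vis)) {
      i <- mrow[ii]
      sb <- dyn$seg2body[[mk$segment[i]]]
      P[ii, ] <- kin$x[sb$body, ] +
        rot2(kin$phi[sb$body]) %*% (sb$off + c(mk$x[i], mk$y[i]))
    }
    list(P = P, kin = kin)
  }

  flagged <- FALSE
  lambda <- 1e-6
  pr <- predict2(q)
  f <- objective(pr$P)
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    # stacked weighted jacobian
    J <- matrix(0, 2L * length(vis), n)
    r <- numeric(2L * length(vis))
    for (ii in seq_along(vis)) {
      i <- mrow[ii]
      sb <- dyn$seg2body[[mk$segment[i]]]
      Ji <- point_jacobian(dyn, pr$kin, sb$body, pr$P[ii, ])
      sw <- sqrt(w[ii])
      J[2L * ii - 1:0, ] <- sw * Ji
      r[2L * ii - 1:0] <- sw * (obs[ii, 1:2] - pr$P[ii, ])
    }
    if (it == 1L && qr(J)$rank < n) {
      flagged <- TRUE
      break
    }
    H <- crossprod(J)
    g <- crossprod(J, r)
    repeat {
      step <- tryCatch(solve(H + lambda * diag(n), g), error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      q_new <- q + as.numeric(step)
      pr_new <- predict2(q_new)
      f_new <- objective(pr_new$P)
      if (f_new <= f + 1e-15) {        # never increase the objective
        lambda <- max(lambda / 10, 1e-10)
        break
      }
      lambda <- lambda * 10
      if (lambda > 1e8) { q_new <- q; pr_new <- pr; f_new <- f; break }
    }
    done <- f - f_new < tol * max(1, f)
    q <- q_new; pr <- pr_new; f <- f_new
    if (done) break
  }
  names(q) <- dyn$coords
  err3 <- sqrt(rowSums((obs - cbind(pr$P, mk$z[mrow]))^2))
  names(err3) <- vis
  list(q = q, errors = err3,
       rmse = sqrt(mean(err3^2)), max_error = max(err3, 0),
       objective = f, flagged = flagged, iterations = iters)
}

#' Solve inverse kinematics over a whole trial
#'
#' Frame loop with warm starts (each frame starts from the previous
#' solution). Frames with long marker gaps or an under-constrained marker
#' set keep the previous frame's coordinates and are flagged. The error
#' report compares the trial RMSE and worst marker error against the
#' guidelines (RMSE < 2 cm, maximum error < 2-4 cm).
#'
#' @param model an \code{msk_model}.
#' @param traj a \code{\link{marker_trajectories}}.
#' @param weights,settings see \code{\link{solve_ik_frame}}; settings may
#'   carry \code{max_marker_error} (default 0.04) and \code{max_rmse}
#'   (default 0.02).
#' @return list with \code{trajectory} (a \code{reference_trajectory}),
#'   \code{rmse}, \code{max_error}, \code{frames_above_max} (times of frames
#'   whose worst marker exceeds the threshold), \code{flagged_frames},
#'   \code{within_guidelines}.
#' @export
solve_ik_trial <- function(model, traj, weights = NULL, settings = list()) {
  dyn <- build_dynamic_tree(model)
  max_err <- settings$max_marker_error %||% 0.04
  max_rmse <- settings$max_rmse %||% 0.02
  nt <- length(traj$times)
  Q <- matrix(0, nt, dyn$n, dimnames = list(NULL, dyn$coords))
  rmse <- numeric(nt); worst <- numeric(nt); flagged <- logical(nt)
  q_prev <- NULL
  traj <- interpolate_marker_gaps(traj)
  for (k in seq_len(nt)) {
    mkpos <- matrix(traj$positions[k, , ], ncol = 3L,
                    dimnames = list(traj$marker_names, c("x", "y", "z")))
    mkpos[traj$missing_mask[k, ], ] <- NA_real_
    sol <- solve_ik_frame(model, mkpos, weights = weights, q0 = q_prev,
                          settings = settings, dyn = dyn)
    if (sol$flagged && !is.null(q_prev)) sol$q <- q_prev
    Q[k, ] <- sol$q
    rmse[k] <- sol$rmse; worst[k] <- sol$max_error; flagged[k] <- sol$flagged
    q_prev <- sol$q
  }
  trial_rmse <- sqrt(mean(rmse^2))
  list(trajectory = reference_trajectory(traj$times, Q),
       rmse = trial_rmse, max_error = max(worst),
       frame_rmse = rmse, frame_max = worst,
       frames_above_max = traj$times[worst > max_err],
       flagged_frames = traj$times[flagged],
       within_guidelines = trial_rmse < max_rmse && max(worst) < max_err)
}
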