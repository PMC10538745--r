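# Sagittal-plane multibody dynamics over the 10 dynamic coordinates
# (pelvis tx/ty/tilt, lumbar extension, hips, knees, ankles). Inverse
# dynamics is a world-frame recursive Newton-Euler pass; the mass matrix is
# assembled by unit-acceleration inverse dynamics, which keeps forward and
# inverse dynamics exactly consistent.

# ext: list of wrenches, each list(body = index or segment name, pt = c(x,y)
# world, F = c(Fx,Fy), Tz = scalar)
rnea <- function(dyn, q, qd, qdd, gravity = TRUE, ext = NULL, kin = NULL) {
  nb <- length(dyn$bodies)
  if (is.null(kin)) kin <- tree_kinematics(dyn, q, qd, qdd)
  g <- if (gravity) c(0, -GRAVITY) else c(0, 0)

  fext <- matrix(0, nb, 2L); next_ <- numeric(nb)
  if (!is.null(ext)) for (w in ext) {
    bi <- if (is.character(w$body)) dyn$seg2body[[w$body]]$body else w$body
    fext[bi, ] <- fext[bi, ] + w$F
    next_[bi] <- next_[bi] + (w$Tz %||% 0) +
      cross2z(w$pt - kin$x[bi, ], w$F)
  }

  f <- matrix(0, nb, 2L)   # joint force from parent on body, world frame
  n <- numeric(nb)         # joint moment about the body origin
  tau <- numeric(dyn$n)
  for (i in rev(seq_len(nb))) {
    b <- dyn$bodies[[i]]
    rc <- as.numeric(rot2(kin$phi[i]) %*% b$com)
    a_c <- kin$a[i, ] + kin$al[i] * perp2(rc) - kin$om[i]^2 * rc
    fi <- b$mass * (a_c - g) - fext[i, ]
    ni <- b$izz * kin$al[i] + cross2z(rc, b$mass * (a_c - g)) - next_[i]
    # children already processed (list is topologically ordered)
    for (j in seq_len(nb)) {
      if (dyn$bodies[[j]]$parent == i) {
        fi <- fi + f[j, ]
        ni <- ni + n[j] + cross2z(kin$x[j, ] - kin$x[i, ], f[j, ])
      }
    }
    f[i, ] <- fi; n[i] <- ni
    if (b$jtype == "float") {
      tau[b$qidx[1L]] <- fi[1L]
      tau[b$qidx[2L]] <- fi[2L]
      tau[b$qidx[3L]] <- b$axis * ni
    } else {
      tau[b$qidx] <- b$axis * ni
    }
  }
  tau
}

# mass matrix by unit-acceleration inverse dynamics (symmetric PD)
mass_matrix <- function(dyn, q) {
  n <- dyn$n
  M <- matrix(0, n, n)
  zero <- numeric(n)
  for (j in seq_len(n)) {
    e <- zero; e[j] <- 1
    M[, j] <- rnea(dyn, q, zero, e, gravity = FALSE)
  }
  (M + t(M)) / 2
}

# velocity + gravity bias: tau needed for qdd = 0 with no external forces
bias_forces <- function(dyn, q, qd) rnea(dyn, q, qd, numeric(dyn$n), gravity = TRUE)

# total generalized force of a set of external wrenches
ext_generalized <- function(dyn, q, ext, kin = NULL) {
  if (is.null(kin)) kin <- tree_kinematics(dyn, q)
  Q <- numeric(dyn$n)
  if (!is.null(ext)) for (w in ext) {
    bi <- if (is.character(w$body)) dyn$seg2body[[w$body]]$body else w$body
    Q <- Q + generalized_external_force(dyn, kin, bi, w$pt, w$F, w$Tz %||% 0)
  }
  Q
}

#' One semi-implicit Euler step of forward dynamics
#'
#' Solves the equations of motion for the generalized accelerations and
#' advances the state with a semi-implicit (symplectic) Euler step:
#' velocities first, then positions with the updated velocities.
#'
#' @param dyn dynamic tree from \code{build_dynamic_tree}.
#' @param state list with \code{q}, \code{qd} (and optionally \code{t}).
#' @param tau applied generalized forces (muscles + actuators), length n.
#' @param ext external wrenches (ground reactions), see \code{rnea}.
#' @param dt time step in s (> 0).
#' @param gravity logical.
#' @return updated state list with \code{q}, \code{qd}, \code{qdd}, \code{t},
#'   and \code{ke} (kinetic energy after the step).
#' @export
forward_dynamics_step <- function(dyn, state, tau = NULL, ext = NULL, dt,
                                  gravity = TRUE) {
  stopifnot(dt > 0)
  q <- state$q; qd <- state$qd
  if (is.null(tau)) tau <- numeric(dyn$n)
  M <- mass_matrix(dyn, q)
  b <- rnea(dyn, q, qd, numeric(dyn$n), gravity = gravity)
  Q <- ext_generalized(dyn, q, ext)
  qdd <- solve(M, tau + Q - b)
  qd2 <- qd + dt * qdd
  q2 <- q + dt * qd2
  list(q = q2, qd = qd2, qdd = qdd, t = (state$t %||% 0) + dt,
       ke = 0.5 * sum(qd2 * (mass_matrix(dyn, q2) %*% qd2)))
}

# ---- trajectory-level inverse dynamics ------------------------------------

# zero-lag low-pass filter (2nd order Butterworth, forward-backward) with
# odd-reflection end padding, applied per column; identity when cutoff <= 0
# or for very short series. Filtering is meant for noisy experimental
# marker data; clean (synthetic) angles differentiate best unfiltered.
lowpass_cols <- function(mat, rate, cutoff = 6) {
  if (is.null(cutoff) || cutoff <= 0 || nrow(mat) < 12L) return(mat)
  bf <- signal::butter(2, min(cutoff / (rate / 2), 0.99))
  n <- nrow(mat)
  np <- min(n - 1L, ceiling(3 * rate / cutoff))
  apply(mat, 2L, function(y) {
    ypad <- c(2 * y[1L] - rev(y[2L:(np + 1L)]), y,
              2 * y[n] - rev(y[(n - np):(n - 1L)]))
    as.numeric(signal::filtfilt(bf, ypad))[np + seq_len(n)]
  })
}

# 4th-order central differences with one-sided ends
diff_central <- function(mat, dt) {
  n <- nrow(mat)
  D <- matrix(0, n, ncol(mat))
  if (n >= 5L) {
    i <- 3:(n - 2L)
    D[i, ] <- (mat[i - 2L, ] - 8 * mat[i - 1L, ] + 8 * mat[i + 1L, ] - mat[i + 2L, ]) / (12 * dt)
  }
  lo <- seq_len(min(2L, n - 1L))
  D[lo, ] <- (mat[lo + 1L, ] - mat[lo, ]) / dt
  hi <- (n - 1L):n; hi <- hi[hi > 2L]
  D[hi, ] <- (mat[hi, ] - mat[hi - 1L, ]) / dt
  D
}

#' Inverse dynamics of a tracked trajectory with ground reactions
#'
#' Runs the recursive Newton-Euler inverse dynamics at every frame of a
#' reference trajectory, applying the measured ground reaction wrenches at
#' their centres of pressure, and reports the per-coordinate generalized
#' forces. The forces at the six pelvis coordinates are the residuals
#' ("hand-of-god" forces); in this sagittal engine they are the pelvis tx,
#' ty and tilt components. The residual report compares the mean absolute
#' residuals against the standard guideline: residual forces below 1\% of
#' the peak net external force magnitude, residual moments below 1\% of the
#' centre-of-mass height times that magnitude.
#'
#' @param model an \code{msk_model}.
#' @param trajectory a \code{reference_trajectory} (see
#'   \code{\link{reference_trajectory}}); if velocities/accelerations are
#'   absent they are computed by low-pass filtering (default 6 Hz cutoff) and
#'   4th-order central differencing.
#' @param grf a \code{forceplate_series} or NULL.
#' @param cutoff low-pass cutoff for numerical differentiation (Hz); 0
#'   (default) differentiates unfiltered, which is exact for noise-free
#'   angles. Use ~6 Hz for angles fitted to noisy experimental markers.
#' @return list with \code{torques} (frames x coords matrix), \code{times},
#'   \code{residuals} (frames x 3: FX, FY, MZ), and \code{residual_report}.
#' @export
inverse_dynamics <- function(model, trajectory, grf = NULL, cutoff = 0) {
  dyn <- build_dynamic_tree(model)
  tr <- as_reference_trajectory(trajectory, dyn$coords, cutoff = cutoff)
  times <- tr$times
  nt <- length(times)
  if (!is.null(grf)) {
    if (max(grf$times) < min(times) || min(grf$times) > max(times))
      stopf("GRF and trajectory time ranges do not overlap")
  }
  tau <- matrix(0, nt, dyn$n, dimnames = list(NULL, dyn$coords))
  for (k in seq_len(nt)) {
    ext <- if (is.null(grf)) NULL else grf_wrenches(model, dyn, grf, times[k])
    tau[k, ] <- rnea(dyn, tr$q[k, ], tr$qd[k, ], tr$qdd[k, ], ext = ext)
  }
  pel <- match(c("pelvis_tx", "pelvis_ty", "pelvis_tilt"), dyn$coords)
  residuals <- tau[, pel, drop = FALSE]
  colnames(residuals) <- c("FX", "FY", "MZ")
  rep <- residual_report(model, residuals, grf, times)
  list(torques = tau, times = times, residuals = residuals,
       residual_report = rep, coords = dyn$coords)
}

# guideline check on pelvis residuals
residual_report <- function(model, residuals, grf, times) {
  fmag <- if (!is.null(grf)) {
    max(sqrt(rowSums(grf_total_force(grf)^2)))
  } else model_mass(model) * GRAVITY
  com_h <- 1.0  # generic standing centre-of-mass height (m)
  f_bound <- 0.01 * fmag
  m_bound <- 0.01 * com_h * fmag
  mean_f <- mean(sqrt(residuals[, "FX"]^2 + residuals[, "FY"]^2))
  mean_m <- mean(abs(residuals[, "MZ"]))
  list(mean_force = mean_f, mean_moment = mean_m,
       force_bound = f_bound, moment_bound = m_bound,
       within_guideline = (mean_f < f_bound) && (mean_m < m_bound))
}

# interpolate the force-plate series at time t and build the wrench list;
# forces are applied to the stance-side foot segment at the centre of pressure
grf_wrenches <- function(model, dyn, grf, t) {
  out <- list()
  for (s in names(grf$plates)) {
    pl <- grf$plates[[s]]
    F <- c(approx(grf$times, pl$force[, 1L], t, rule = 2)$y,
           approx(grf$times, pl$force[, 2L], t, rule = 2)$y)
    if (sqrt(sum(F^2)) < 1e-9) next
    pt <- c(approx(grf$times, pl$cop[, 1L], t, rule = 2)$y,
            approx(grf$times, pl$cop[, 2L], t, rule = 2)$y)
    Tz <- approx(grf$times, pl$torque, t, rule = 2)$y
    seg <- foot_segment(model, s)
    out[[length(out) + 1L]] <- list(body = seg, pt = pt, F = F, Tz = Tz)
  }
  out
}

foot_segment <- function(model, side) {
  cand <- c(paste0("pros_foot_", side), paste0("foot_", side))
  cand[cand %in% model$segments$name][1L]
}

grf_total_force <- function(grf) {
  tot <- matrix(0, length(grf$times), 2L)
  for (pl in grf$plates) tot <- tot + pl$force[, 1:2, drop = FALSE]
  tot
}
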