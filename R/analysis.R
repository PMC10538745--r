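# Post-processing: gait events from vertical ground reaction force,
# normalization of signals to the 0-100% gait cycle, joint power and
# per-cycle energy normalized to body mass, and muscle-group force
# summaries.

#' Detect heel-strike and toe-off events from vertical GRF
#'
#' Rising/falling threshold crossings (default 20 N) with hysteresis: after
#' a rising crossing the signal must fall below half the threshold to arm
#' the next event.
#'
#' @param grf a \code{\link{forceplate_series}}.
#' @param threshold force threshold (N).
#' @return list per side with \code{heel_strikes} and \code{toe_offs}
#'   (times, s).
#' @export
detect_gait_events <- function(grf, threshold = 20) {
  out <- list()
  for (s in names(grf$plates)) {
    fy <- grf$plates[[s]]$force[, 2L]
    hi <- fy > threshold
    lo <- fy < threshold / 2
    hs <- numeric(0); to <- numeric(0)
    armed <- !hi[1L]
    loaded <- hi[1L]
    for (k in 2L:length(fy)) {
      if (armed && hi[k] && !hi[k - 1L]) {
        hs <- c(hs, grf$times[k]); armed <- FALSE; loaded <- TRUE
      }
      if (loaded && !hi[k] && hi[k - 1L]) {
        to <- c(to, grf$times[k]); loaded <- FALSE
      }
      if (!armed && lo[k]) armed <- TRUE
    }
    out[[s]] <- list(heel_strikes = hs, toe_offs = to)
  }
  out
}

#' Joint power normalized to body mass
#'
#' @param torque torque series (N.m).
#' @param qd angular velocity series (rad/s), aligned with \code{torque}.
#' @param body_mass subject mass (kg).
#' @return power in W/kg.
#' @examples
#' joint_power(10, 2, 50)  # 0.4 W/kg
#' @export
joint_power <- function(torque, qd, body_mass) torque * qd / body_mass

#' Energy over a gait cycle
#'
#' Trapezoidal time integral of a mass-normalized power series over one
#' cycle window.
#'
#' @param times seconds.
#' @param power W/kg series.
#' @param window c(start, end) in seconds (default: whole series).
#' @return energy in J/kg.
#' @export
energy_per_cycle <- function(times, power, window = range(times)) {
  sel <- times >= window[1L] & times <= window[2L]
  trapz_int(times[sel], power[sel])
}

#' Summed force of a functional muscle group
#'
#' Sums the fiber forces of the group members on one side; removed members
#' are absent from the roster and disabled-anchored members contribute
#' exactly zero, so an amputated-side group whose members are all removed
#' sums to an identically zero series.
#'
#' @param model an \code{msk_model}.
#' @param activations matrix (frames x muscle names) of activations.
#' @param trajectory the matching \code{reference_trajectory} (for fiber
#'   kinematics).
#' @param group group name in \code{\link{muscle_groups}} or a character
#'   vector of anatomical muscle names.
#' @param side "r" or "l".
#' @return numeric force series (N).
#' @export
muscle_group_force <- function(model, activations, trajectory, group,
                               side = "r") {
  roster <- if (length(group) == 1L && group %in% names(muscle_groups()))
    muscle_groups()[[group]] else group
  mus <- model$muscles
  base_nosuffix <- sub("[0-9]+$", "", mus$base)
  members <- mus$name[mus$side == side &
                      (mus$base %in% roster | base_nosuffix %in% roster)]
  dyn <- build_dynamic_tree(model)
  tr <- as_reference_trajectory(trajectory, dyn$coords)
  R <- muscle_arm_matrix(model, dyn$coords)
  nt <- length(tr$times)
  out <- numeric(nt)
  if (!length(members)) return(out)
  mi <- match(members, mus$name)
  for (k in seq_len(nt)) {
    fs <- muscle_fiber_state(model, tr$q[k, ], tr$qd[k, ], R = R)
    a <- rep(0, nrow(mus))
    hit <- match(mus$name, colnames(activations))
    a[!is.na(hit)] <- activations[min(k, nrow(activations)), hit[!is.na(hit)]]
    f <- fiber_force(mus$F0, a, fs$l_norm, fs$v_norm, mus$status)
    out[k] <- sum(f[mi])
  }
  out
}

#' Packaged functional muscle groups
#'
#' Editable rosters of the hip flexor/extensor, knee flexor/extensor,
#' plantarflexor and dorsiflexor groups (anatomical names; numbered units
#' are matched by prefix).
#'
#' @return named list of character vectors.
#' @export
muscle_groups <- function() og_muscle_groups()

#' Resample a signal to the 0-100% gait cycle
#'
#' Interpolates a time series onto 101 evenly spaced points of each gait
#' cycle delimited by consecutive heel strikes and reports the per-point
#' mean and standard deviation across cycles.
#'
#' @param times seconds.
#' @param signal numeric series.
#' @param heel_strikes cycle start times (>= 2, or 1 start plus
#'   \code{cycle}).
#' @param cycle optional cycle duration used when a single heel strike is
#'   given.
#' @return object of class \code{gait_cycle_series}: list with
#'   \code{percent} (0..100), \code{cycles} (matrix cycles x 101),
#'   \code{mean}, \code{sd}.
#' @export
to_gait_cycle <- function(times, signal, heel_strikes, cycle = NULL) {
  if (length(heel_strikes) < 2L) {
    if (is.null(cycle)) stopf("need >= 2 heel strikes or an explicit cycle duration")
    heel_strikes <- c(heel_strikes, heel_strikes + cycle)
  }
  pct <- seq(0, 100, length.out = 101L)
  n_cyc <- length(heel_strikes) - 1L
  M <- matrix(NA_real_, n_cyc, 101L)
  for (i in seq_len(n_cyc)) {
    tt <- seq(heel_strikes[i], heel_strikes[i + 1L], length.out = 101L)
    M[i, ] <- approx(times, signal, xout = tt, rule = 2)$y
  }
  structure(list(percent = pct, cycles = M,
                 mean = colMeans(M),
                 sd = if (n_cyc > 1L) apply(M, 2L, sd) else rep(0, 101L)),
            class = "gait_cycle_series")
}

#' @export
print.gait_cycle_series <- function(x, ...) {
  cat(sprintf("<gait_cycle_series: %d cycle(s), mean range [%.3g, %.3g]>\n",
              nrow(x$cycles), min(x$mean), max(x$mean)))
  invisible(x)
}

#' @export
plot.gait_cycle_series <- function(x, ylab = "signal", main = "", ...) {
  plot(x$percent, x$mean, type = "l", xlab = "gait cycle (%)", ylab = ylab,
       main = main, ...)
  if (any(x$sd > 0)) {
    graphics::polygon(c(x$percent, rev(x$percent)),
                      c(x$mean + x$sd, rev(x$mean - x$sd)),
                      border = NA, col = grDevices::adjustcolor("grey", 0.5))
    graphics::lines(x$percent, x$mean)
  }
  invisible(x)
}
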