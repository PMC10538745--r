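# Residual reduction: adjust the model's mass distribution so that inverse
# dynamics of a tracked trial needs the smallest possible "hand-of-god"
# pelvis residuals. Mirrors the standard residual-reduction practice: a
# uniform segment-mass rescaling absorbs the mean vertical residual force
# and a fore-aft shift of the torso centre of mass absorbs the mean pelvis
# moment. Both updates are solved jointly by a damped Newton iteration on
# the two mean residuals, with finite-difference sensitivities.

#' Reduce pelvis residuals by adjusting model mass and torso COM
#'
#' Iteratively rescales all segment masses by a common factor and shifts the
#' torso centre of mass fore-aft until the mean pelvis residual force (FY)
#' and moment (MZ) vanish or the iteration cap is reached. Reports the
#' signed total mass change and whether the adjusted model meets the 1\%
#' residual guideline; non-convergence is flagged, never silent.
#'
#' @param model an \code{msk_model}.
#' @param trajectory a \code{reference_trajectory} of the tracked motion.
#' @param grf the measured \code{forceplate_series}.
#' @param max_iter Newton iteration cap.
#' @param tol convergence tolerance on the mass-factor/COM updates.
#' @return list with \code{model} (adjusted), \code{mass_change} (kg,
#'   signed), \code{torso_com_shift} (m), \code{residual_report} (after
#'   adjustment), \code{converged}, \code{iterations}.
#' @export
residual_reduction <- function(model, trajectory, grf, max_iter = 8,
                               tol = 1e-4) {
  mass0 <- model_mass(model)

  apply_p <- function(p) {
    # p = (log mass factor, torso com x shift)
    m2 <- model
    f <- exp(p[1L])
    m2$segments$mass <- m2$segments$mass * f
    m2$segments$izz <- m2$segments$izz * f
    i <- which(m2$segments$name == "torso")
    if (length(i)) m2$segments$com_x[i] <- m2$segments$com_x[i] + p[2L]
    m2
  }
  resid <- function(p) {
    id <- inverse_dynamics(apply_p(p), trajectory, grf)
    c(FY = mean(id$residuals[, "FY"]), MZ = mean(id$residuals[, "MZ"]))
  }

  p <- c(0, 0)
  r <- resid(p)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    h <- c(2e-3, 2e-3)
    J <- matrix(0, 2L, 2L)
    for (j in 1:2) {
      dp <- p; dp[j] <- dp[j] + h[j]
      J[, j] <- (resid(dp) - r) / h[j]
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    step <- clamp(step, -0.2, 0.2)
    p <- p + step
    r <- resid(p)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  adjusted <- apply_p(p)
  id <- inverse_dynamics(adjusted, trajectory, grf)
  if (!converged && max(abs(r)) < 1e-6 * mass0 * GRAVITY) converged <- TRUE
  list(model = adjusted,
       mass_change = model_mass(adjusted) - mass0,
       torso_com_shift = p[2L],
       residual_report = id$residual_report,
       converged = converged, iterations = it)
}
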