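# Shared fixtures, built once per test run and memoised. Everything is
# generated in code; no binary fixtures.

.shared <- new.env(parent = emptyenv())

shared <- function(name, build) {
  if (is.null(.shared[[name]])) .shared[[name]] <- build()
  .shared[[name]]
}

amputee_model <- function() shared("amputee", function() {
  apply_amputation(build_healthy_model())
})

healthy_locked <- function() shared("healthy_locked", function() {
  lock_coordinates(build_healthy_model(),
                   c("subtalar_angle_r", "mtp_angle_r",
                     "subtalar_angle_l", "mtp_angle_l"))
})

# one noiseless amputee cycle under the default study conditions
amputee_trial <- function() shared("trial", function() {
  generate_consistent_trial(amputee_model(), gait_spec())
})

amputee_id <- function() shared("id", function() {
  tr <- amputee_trial()
  inverse_dynamics(amputee_model(), tr$reference, tr$grf)
})

# full-cycle forward simulation under modified computed muscle control
amputee_mcmc <- function() shared("mcmc", function() {
  tr <- amputee_trial()
  run_mcmc(amputee_model(), tr$reference, tr$grf)
})

# 1-DOF toy: a hanging rod driven by one flexor/extensor pair whose
# floor-level co-contraction torques cancel
toy_pendulum_model <- function(with_muscles = TRUE) {
  segs <- data.frame(name = "rod", parent = "ground", joint = "hip_r",
                     jtype = "rev", axis = 1, loc_x = 0, loc_y = 0,
                     mass = 5, com_x = 0, com_y = -0.2, izz = 0.1)
  coords <- data.frame(name = "hip_flexion_r", joint = "hip_r", kind = "rot",
                       sagittal = TRUE, segment = "rod", locked = FALSE)
  mus <- NULL
  if (with_muscles) {
    mus <- data.frame(
      name = c("flex_r", "ext_r"), base = c("flex", "ext"),
      side = "r", group = "leg",
      F0 = c(1000, 800), lopt = 0.1, lslack = 0.2, vmax = 10,
      r_hip = c(0.04, -0.05), r_knee = 0, r_ankle = 0, r_lumbar = 0,
      status = "active")
  }
  msk_model(segs, coords, muscles = mus, name = "toy_pendulum")
}

expect_no_error <- function(expr) expect_error(expr, NA)

`%||%` <- function(a, b) if (is.null(a)) b else a
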