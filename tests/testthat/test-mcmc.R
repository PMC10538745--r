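test_that("the tracking law reduces to the reference when error vanishes", {
  m <- amputee_model()
  coords <- dynamic_coords(m)
  spec <- gait_spec()
  ref_traj <- generate_reference_kinematics(m, spec)
  gains <- tracking_gains(m)
  ref <- osseogait:::ref_interpolator(ref_traj, names(gains$kp))
  t <- 0.30
  state <- list(q = ref(t, "q"), qd = ref(t, "qd"))
  qdd_des <- desired_accelerations(ref, state, gains, t, lookahead = 0.001)
  expect_equal(unname(qdd_des), unname(ref(t + 0.001, "qdd")),
               tolerance = 1e-6)
  # a pure position error e enters as kp * e
  e <- 0.02
  state2 <- state
  state2$q["hip_flexion_l"] <- state2$q["hip_flexion_l"] - e
  qdd2 <- desired_accelerations(ref, state2, gains, t, lookahead = 0.001)
  expect_equal(unname(qdd2["hip_flexion_l"] - qdd_des["hip_flexion_l"]),
               100 * e, tolerance = 1e-9)
  # prosthetic coordinates carry the actuator gains 1000 / 90
  expect_equal(unname(gains$kp[c("pros_knee", "pros_ankle")]), c(1000, 1000))
  expect_equal(unname(gains$kv[c("pros_knee", "pros_ankle")]), c(90, 90))
  expect_equal(unname(gains$kp["hip_flexion_l"]), 100)
  expect_equal(unname(gains$kv["knee_angle_l"]), 20)
})

# a hand-built 1-DOF allocation problem: one muscle + one reserve
toy_allocation <- function(gain = 200, arm = 0.04, I = 0.1, qdd0 = -3,
                           tau_res = 1) {
  G <- matrix(c(gain * arm / I, tau_res / I), 1, 2)
  list(G = G, qdd0 = qdd0, d = c(1 / 1000^2, 1 / tau_res^2),
       lb = c(0.02, 0), ub = c(1, 1), B = G * I,
       tau_pass = 0, M = matrix(I, 1, 1), bias = 0, Q = 0,
       gain = gain, passive = 0,
       n_muscles = 1L, n_actuators = 0L, n_reserves = 1L,
       coords = "joint", effectors = c("muscle", "reserve"))
}

test_that("allocation matches a brute-force grid on the 1-DOF toy plant", {
  p <- toy_allocation()
  qdd_des <- 5
  sol <- allocate_controls(p, qdd_des, weights = 1)
  g <- seq(0, 1, by = 0.001)
  best <- c(Inf, NA, NA)
  for (a in g[g >= 0.02]) {
    J <- (a / 1000)^2 + g^2 +
      (qdd_des - (p$qdd0 + p$G[1] * a + p$G[2] * g))^2
    i <- which.min(J)
    if (J[i] < best[1]) best <- c(J[i], a, g[i])
  }
  expect_lt(max(abs(unname(sol$x) - best[2:3])), 1e-3)
  expect_true(sol$feasible)
})

test_that("exactly achievable demands leave only the effort term in J", {
  p <- toy_allocation()
  # pick a demand the muscle can satisfy exactly within bounds
  a_star <- 0.4
  qdd_des <- p$qdd0 + p$G[1] * a_star
  sol <- allocate_controls(p, qdd_des, weights = 1)
  expect_lt(sol$J_track / max(sol$J, 1e-12), 1e-4)
  expect_equal(sol$J, sol$J_effort + sol$J_track, tolerance = 1e-12)
})

test_that("zero task weights are rejected", {
  expect_error(allocate_controls(toy_allocation(), 1, weights = 0),
               "weights")
})

test_that("prosthesis demands are served without waking the reserves", {
  m <- amputee_model()
  dyn <- osseogait:::build_dynamic_tree(m)
  coords <- dyn$coords
  spec <- gait_spec()
  ref_traj <- generate_reference_kinematics(m, spec)
  ref <- osseogait:::ref_interpolator(ref_traj, coords)
  t <- 0.25
  p <- osseogait:::mcmc_allocation_problem(m, dyn, ref(t, "q"), ref(t, "qd"),
                                           amputee_trial()$grf, t)
  qdd_des <- ref(t, "qdd")
  qdd_des["pros_knee"] <- qdd_des["pros_knee"] + 50  # big prosthetic demand
  sol <- allocate_controls(p, qdd_des, weights = 1)
  res_t <- abs(sol$reserve_controls) * 1  # reserve torques, N.m
  act_t <- max(abs(sol$actuator_controls) * 1e6)
  expect_gt(act_t, 1)
  expect_lt(max(res_t[c("reserve_pros_knee", "reserve_knee_angle_l",
                        "reserve_hip_flexion_r")]) / act_t, 1e-3)
})

test_that("regulation about a stable equilibrium holds to 1e-4 rad", {
  m <- toy_pendulum_model()
  times <- seq(0, 0.4, by = 0.01)
  q <- matrix(0, length(times), 1, dimnames = list(NULL, "hip_flexion_r"))
  ref <- reference_trajectory(times, q, qd = q * 0, qdd = q * 0)
  mc <- run_mcmc(m, ref, grf = NULL)
  expect_false(mc$diverged)
  expect_lt(max(abs(mc$q)), 1e-4)
})

test_that("tracking improves monotonically with kp on the toy plant", {
  m <- toy_pendulum_model()
  times <- seq(0, 0.5, by = 0.01)
  q <- matrix(0.08 * sin(2 * pi * times / 0.5), ncol = 1,
              dimnames = list(NULL, "hip_flexion_r"))
  qd <- matrix(0.08 * 2 * pi / 0.5 * cos(2 * pi * times / 0.5), ncol = 1,
               dimnames = list(NULL, "hip_flexion_r"))
  qdd <- matrix(-0.08 * (2 * pi / 0.5)^2 * sin(2 * pi * times / 0.5),
                ncol = 1, dimnames = list(NULL, "hip_flexion_r"))
  ref <- reference_trajectory(times, q, qd, qdd)
  errs <- sapply(c(25, 100, 400), function(kp) {
    cfg <- run_config(mcmc = list(kp_muscle = kp,
                                  kv_muscle = 2 * sqrt(kp)))$mcmc
    mean(abs(run_mcmc(m, ref, grf = NULL, cfg = cfg)$tracking))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("full-cycle amputee simulation tracks below half a degree", {
  mc <- amputee_mcmc()
  expect_false(mc$diverged)
  expect_true(all(mc$tracking_deg < 0.5))
  # muscles carry first-order activation dynamics: activation steps are
  # bounded by the rise-rate limit, while actuator torque may jump freely
  da <- abs(diff(mc$activations))
  expect_lt(max(da), 1 - exp(-0.001 / 0.010) + 1e-9)
  # the stateless prosthesis actuators deliver working torques throughout
  expect_gt(max(abs(mc$actuator_torques)), 50)
})

test_that("reserves stay negligible relative to the prosthesis actuators", {
  mc <- amputee_mcmc()
  expect_lt(mc$reserve_report$muscle_joint_reserve_ratio, 1e-3)
  expect_gt(mc$reserve_report$peak_actuator_torque, 50)
})

test_that("disabling the prosthesis actuators saturates the reserves", {
  m <- amputee_model()
  trial <- amputee_trial()
  enabled <- amputee_mcmc()
  m2 <- m
  m2$actuators <- NULL
  mc <- run_mcmc(m2, trial$reference, trial$grf, t_end = 0.3)
  # the 1 N.m reserves saturate at the prosthetic joints
  expect_gte(max(mc$reserve_torques[, c("reserve_pros_knee",
                                        "reserve_pros_ankle")], na.rm = TRUE),
             1 - 1e-6)
  # and tracking of the prosthetic coordinates collapses
  expect_gt(max(mc$tracking_deg[c("pros_knee", "pros_ankle")]),
            10 * max(enabled$tracking_deg[c("pros_knee", "pros_ankle")]))
})
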