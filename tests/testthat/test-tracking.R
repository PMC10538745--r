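test_that("noiseless inverse kinematics recovers the generating pose exactly", {
  m <- amputee_model()
  dyn <- osseogait:::build_dynamic_tree(m)
  set.seed(5)
  qstar <- runif(dyn$n, -0.3, 0.3)
  qstar[match(c("pelvis_tx", "pelvis_ty"), dyn$coords)] <- c(0.1, 0.95)
  fk <- forward_kinematics(m, qstar, dyn = dyn)
  sol <- solve_ik_frame(m, fk$markers)
  expect_lt(max(abs(sol$q[dyn$coords] - qstar)), 1e-8)
  expect_lt(sol$rmse, 1e-10)
  expect_false(sol$flagged)
})

test_that("IK on a noisy trial meets the 2 cm RMSE guideline", {
  m <- amputee_model()
  trial <- generate_consistent_trial(m, gait_spec(marker_noise = 0.003,
                                                  cycles = 2L, seed = 7))
  ik <- solve_ik_trial(m, trial$markers)
  expect_lt(ik$rmse, 0.02)
  expect_lt(ik$max_error, 0.04)
  expect_true(ik$within_guidelines)
  # recovered joint angles stay close to the generating reference
  shared_cols <- colnames(trial$reference$q)
  err <- abs(ik$trajectory$q[, shared_cols] - trial$reference$q[, shared_cols])
  expect_lt(mean(err), 0.05)
})

test_that("raising a marker's weight pulls the fit toward that marker", {
  m <- amputee_model()
  dyn <- osseogait:::build_dynamic_tree(m)
  q0 <- setNames(numeric(dyn$n), dyn$coords)
  q0["pelvis_ty"] <- 0.93
  fk <- forward_kinematics(m, q0, dyn = dyn)
  obs <- fk$markers
  obs["LKNE", 1] <- obs["LKNE", 1] + 0.05  # displace one marker
  w <- ik_default_weights(m)
  errs <- sapply(c(1, 5, 25, 125), function(wk) {
    w2 <- w; w2["LKNE"] <- wk
    solve_ik_frame(m, obs, weights = w2, q0 = q0)$errors["LKNE"]
  })
  expect_true(all(diff(errs) < 0))  # monotone decrease with weight
})

test_that("constant-pose trials give constant angles and threshold flags work", {
  m <- amputee_model()
  dyn <- osseogait:::build_dynamic_tree(m)
  q0 <- setNames(numeric(dyn$n), dyn$coords)
  q0["pelvis_ty"] <- 0.93
  fk <- forward_kinematics(m, q0, dyn = dyn)
  nmk <- nrow(m$markers)
  pos <- aperm(array(fk$markers, c(nmk, 3, 4)), c(3, 1, 2))
  traj <- marker_trajectories(m$markers$name, seq(0, 0.03, by = 0.01),
                              pos, 100)
  ik <- solve_ik_trial(m, traj)
  expect_lt(max(apply(ik$trajectory$q, 2, function(x) diff(range(x)))), 1e-9)
  expect_length(ik$frames_above_max, 0L)
  # push one frame's marker far out: that frame must be reported
  pos2 <- pos; pos2[2, 1, 1] <- pos2[2, 1, 1] + 0.2
  traj2 <- marker_trajectories(m$markers$name, seq(0, 0.03, by = 0.01),
                               pos2, 100)
  ik2 <- solve_ik_trial(m, traj2)
  expect_true(traj$times[2] %in% ik2$frames_above_max)
})

test_that("an under-constrained frame is flagged and holds the previous pose", {
  m <- amputee_model()
  dyn <- osseogait:::build_dynamic_tree(m)
  q0 <- setNames(numeric(dyn$n), dyn$coords); q0["pelvis_ty"] <- 0.93
  fk <- forward_kinematics(m, q0, dyn = dyn)
  obs <- fk$markers
  obs[!(rownames(obs) %in% c("RASI", "LASI", "SACR")), ] <- NA_real_
  sol <- solve_ik_frame(m, obs, q0 = q0)
  expect_true(sol$flagged)
  expect_equal(as.numeric(sol$q), as.numeric(q0), tolerance = 1e-12)
})

test_that("scaling recovers identity and uniform inflation", {
  m <- amputee_model()
  q0 <- setNames(numeric(length(dynamic_coords(m))), dynamic_coords(m))
  q0["pelvis_ty"] <- 0.95
  nmk <- nrow(m$markers)
  static_of <- function(mod) {
    fk <- forward_kinematics(mod, q0)
    pos <- aperm(array(fk$markers, c(nmk, 3, 3)), c(3, 1, 2))
    marker_trajectories(mod$markers$name, c(0, 0.01, 0.02), pos, 100)
  }
  sc <- scale_model(m, static_of(m))
  expect_equal(unname(range(sc$scale_set$factors)), c(1, 1), tolerance = 1e-9)
  expect_lt(sc$scale_set$rmse, 1e-9)
  expect_true(sc$scale_set$within_guideline)

  infl <- m
  for (col in c("loc_x", "loc_y", "com_x", "com_y"))
    infl$segments[[col]] <- infl$segments[[col]] * 1.1
  for (col in c("x", "y", "z"))
    infl$markers[[col]] <- infl$markers[[col]] * 1.1
  sc2 <- scale_model(m, static_of(infl), subject_mass = 80)
  expect_equal(unname(range(sc2$scale_set$factors)), c(1.1, 1.1),
               tolerance = 1e-6)
  expect_equal(model_mass(sc2$model), 80, tolerance = 1e-9)
  # inertias scale with factor^2 (times the mass ratio)
  i_knee <- which(sc2$model$segments$name == "tibia_l")
  expect_equal(sc2$model$segments$izz[i_knee],
               m$segments$izz[i_knee] * 1.1^2 * 80 / model_mass(m),
               tolerance = 1e-6)
})

test_that("scaling weights default to 5 on bony landmarks and 1 upper body", {
  m <- amputee_model()
  w <- scale_default_weights(m)
  expect_equal(unname(w["RKNE"]), 5)
  expect_equal(unname(w["LANK"]), 5)
  expect_equal(unname(w["C7"]), 1)
  expect_equal(unname(w["RSHO"]), 1)
  # inverse-kinematics weights reverse the ordering: segment markers high
  wik <- ik_default_weights(m)
  expect_gt(unname(wik["RTHI"]), unname(wik["RASI"]))
})

test_that("degenerate marker-pair distances abort scaling", {
  m <- amputee_model()
  q0 <- setNames(numeric(length(dynamic_coords(m))), dynamic_coords(m))
  fk <- forward_kinematics(m, q0)
  nmk <- nrow(m$markers)
  pos <- aperm(array(fk$markers, c(nmk, 3, 3)), c(3, 1, 2))
  pos[, match("LASI", m$markers$name), ] <- pos[, match("RASI", m$markers$name), ]
  st <- marker_trajectories(m$markers$name, c(0, 0.01, 0.02), pos, 100)
  expect_error(scale_model(m, st), "degenerate")
})
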