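test_that("forward kinematics matches its defining geometry", {
  m <- amputee_model()
  dyn <- osseogait:::build_dynamic_tree(m)
  q0 <- setNames(numeric(dyn$n), dyn$coords)
  fk0 <- forward_kinematics(m, q0)
  # reference pose: pelvis markers sit at their local definitions
  mk <- m$markers
  for (nm in c("RASI", "LASI", "SACR")) {
    i <- match(nm, mk$name)
    expect_equal(as.numeric(fk0$markers[nm, ]),
                 c(mk$x[i], mk$y[i], mk$z[i]), tolerance = 1e-12)
  }
  # pure pelvis translation shifts every marker equally
  q1 <- q0; q1["pelvis_tx"] <- 0.3; q1["pelvis_ty"] <- 0.1
  fk1 <- forward_kinematics(m, q1)
  d <- fk1$markers - fk0$markers
  expect_lt(max(abs(d[, 1] - 0.3)), 1e-12)
  expect_lt(max(abs(d[, 2] - 0.1)), 1e-12)
  expect_lt(max(abs(d[, 3])), 1e-12)
  # hip flexion rotates thigh markers about the hip centre by exactly delta
  delta <- 0.4
  q2 <- q0; q2["hip_flexion_l"] <- delta
  fk2 <- forward_kinematics(m, q2)
  hip <- c(-0.0707, -0.0661)
  for (nm in c("LTHI", "LKNE")) {
    v0 <- as.numeric(fk0$markers[nm, 1:2]) - hip
    v2 <- as.numeric(fk2$markers[nm, 1:2]) - hip
    ang <- atan2(v2[2], v2[1]) - atan2(v0[2], v0[1])
    expect_equal(ang %% (2 * pi), delta %% (2 * pi), tolerance = 1e-10)
    expect_equal(sqrt(sum(v2^2)), sqrt(sum(v0^2)), tolerance = 1e-12)
  }
})

test_that("mass matrix is symmetric positive definite at random poses", {
  m <- amputee_model()
  dyn <- osseogait:::build_dynamic_tree(m)
  set.seed(11)
  for (i in 1:5) {
    q <- runif(dyn$n, -0.5, 0.5)
    M <- osseogait:::mass_matrix(dyn, q)
    expect_equal(M, t(M), tolerance = 1e-10)
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("inverse dynamics inverts forward dynamics on random torques", {
  m <- amputee_model()
  dyn <- osseogait:::build_dynamic_tree(m)
  set.seed(3)
  state <- list(q = runif(dyn$n, -0.3, 0.3), qd = runif(dyn$n, -1, 1), t = 0)
  for (i in 1:20) {
    tau <- runif(dyn$n, -30, 30)
    st2 <- forward_dynamics_step(dyn, state, tau = tau, dt = 1e-3)
    tau_back <- osseogait:::rnea(dyn, state$q, state$qd, st2$qdd)
    expect_lt(max(abs(tau_back - tau)) / max(1, max(abs(tau))), 1e-6)
    state <- st2
  }
})

test_that("a free body under no force and no gravity moves uniformly", {
  segs <- data.frame(name = "block", parent = "ground", joint = "root",
                     jtype = "float", axis = 1, loc_x = 0, loc_y = 0,
                     mass = 2, com_x = 0, com_y = 0, izz = 0.05)
  coords <- data.frame(name = c("x", "y", "rot"), joint = "root",
                       kind = c("trans", "trans", "rot"), sagittal = TRUE,
                       segment = "block", locked = FALSE)
  m <- msk_model(segs, coords)
  dyn <- osseogait:::build_dynamic_tree(m)
  st <- list(q = c(0, 0, 0), qd = c(0.3, -0.2, 1.5), t = 0)
  for (k in 1:100) st <- forward_dynamics_step(dyn, st, dt = 1e-3,
                                               gravity = FALSE)
  expect_equal(st$qd, c(0.3, -0.2, 1.5), tolerance = 1e-10)
  expect_equal(st$q, c(0.03, -0.02, 0.15), tolerance = 1e-9)
})

test_that("pendulum small oscillations match the closed-form period", {
  m <- toy_pendulum_model(with_muscles = FALSE)
  dyn <- osseogait:::build_dynamic_tree(m)
  l <- 0.2; mass <- 5; izz_joint <- 0.1 + mass * l^2
  T_exact <- 2 * pi * sqrt(izz_joint / (mass * osseogait:::GRAVITY * l))
  dt <- 1e-4
  st <- list(q = 0.01, qd = 0, t = 0)
  crossings <- numeric(0)
  prev <- st$q
  for (k in 1:(3.5 * T_exact / dt)) {
    st <- forward_dynamics_step(dyn, st, dt = dt)
    if (prev < 0 && st$q >= 0)
      crossings <- c(crossings, st$t - dt * st$q / (st$q - prev))
    prev <- st$q
  }
  expect_gte(length(crossings), 3L)
  T_meas <- mean(diff(crossings))
  expect_lt(abs(T_meas - T_exact) / T_exact, 1e-3)
})

test_that("static standing yields gravity torques and zero pelvis residuals", {
  m <- amputee_model()
  dyn <- osseogait:::build_dynamic_tree(m)
  coords <- dyn$coords
  nq <- dyn$n
  q0 <- setNames(numeric(nq), coords); q0["pelvis_ty"] <- 0.95
  times <- seq(0, 0.05, by = 0.01)
  Q <- matrix(rep(q0, each = length(times)), length(times), nq,
              dimnames = list(NULL, coords))
  Z <- Q * 0
  tr <- reference_trajectory(times, Q, qd = Z, qdd = Z)
  # GRF: body weight split under the two feet at the model's foot points
  bw <- model_mass(m) * osseogait:::GRAVITY
  # place the shared COP so the total wrench about the pelvis matches gravity
  resid <- osseogait:::rnea(dyn, q0, q0 * 0, q0 * 0)[1:3]
  com_x <- resid[3] / (-1) / resid[2]  # tilt residual over Fy, pelvis at x=0
  nt <- length(times)
  plates <- list(
    r = list(force = cbind(0, rep(bw / 2, nt), 0),
             cop = cbind(rep(com_x, nt), 0, 0), torque = rep(0, nt)),
    l = list(force = cbind(0, rep(bw / 2, nt), 0),
             cop = cbind(rep(com_x, nt), 0, 0), torque = rep(0, nt)))
  grf <- forceplate_series(times, plates, 100)
  id <- inverse_dynamics(m, tr, grf)
  expect_lt(mean(abs(id$residuals[, "FY"])), 1e-6 * bw)
  expect_lt(mean(abs(id$residuals[, "FX"])), 1e-6 * bw)
  expect_lt(mean(abs(id$residuals[, "MZ"])), 1e-6 * bw)
  # joint torques equal pure gravitational terms at zero acceleration
  tau_grav <- osseogait:::rnea(dyn, q0, q0 * 0, q0 * 0) -
    osseogait:::ext_generalized(dyn, q0,
      list(list(body = "pros_foot_r", pt = c(com_x, 0), F = c(0, bw / 2), Tz = 0),
           list(body = "foot_l", pt = c(com_x, 0), F = c(0, bw / 2), Tz = 0)))
  expect_lt(max(abs(id$torques[1, ] - tau_grav)), 1e-8)
})

test_that("applied wrenches change momentum consistently (weld composite)", {
  # prosthesis-side chain includes the femur+implant weld composite
  m <- amputee_model()
  dyn <- osseogait:::build_dynamic_tree(m)
  momentum_x <- function(q, qd) {
    kin <- osseogait:::tree_kinematics(dyn, q, qd)
    p <- 0
    for (i in seq_along(dyn$bodies)) {
      b <- dyn$bodies[[i]]
      rc <- osseogait:::rot2(kin$phi[i]) %*% b$com
      v_c <- kin$v[i, ] + kin$om[i] * c(-rc[2], rc[1])
      p <- p + b$mass * v_c[1]
    }
    p
  }
  # differential form: at any state, d(sum m v)/dt equals the applied force
  set.seed(9)
  q <- runif(dyn$n, -0.3, 0.3); qd <- runif(dyn$n, -1, 1)
  wrench <- list(list(body = "pros_foot_r", pt = c(0.1, 0.2),
                      F = c(40, -10), Tz = 3))
  M <- osseogait:::mass_matrix(dyn, q)
  b <- osseogait:::rnea(dyn, q, qd, numeric(dyn$n), gravity = FALSE)
  Q <- osseogait:::ext_generalized(dyn, q, wrench)
  qdd <- solve(M, Q - b)
  kin <- osseogait:::tree_kinematics(dyn, q, qd, qdd)
  Fsum <- c(0, 0)
  for (i in seq_along(dyn$bodies)) {
    bb <- dyn$bodies[[i]]
    rc <- osseogait:::rot2(kin$phi[i]) %*% bb$com
    a_c <- kin$a[i, ] + kin$al[i] * c(-rc[2], rc[1]) - kin$om[i]^2 * rc
    Fsum <- Fsum + bb$mass * a_c
  }
  expect_equal(as.numeric(Fsum), c(40, -10), tolerance = 1e-9)

  # integral form over a short window at a fine step
  st <- list(q = numeric(dyn$n), qd = numeric(dyn$n), t = 0)
  Fx <- 40; dt <- 1e-5; nsteps <- 1000
  push <- list(list(body = "pros_foot_r", pt = c(0, 0), F = c(Fx, 0), Tz = 0))
  for (k in 1:nsteps) st <- forward_dynamics_step(dyn, st, ext = push,
                                                  dt = dt, gravity = FALSE)
  expect_equal(momentum_x(st$q, st$qd), Fx * dt * nsteps, tolerance = 0.02)
})
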