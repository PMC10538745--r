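# helper building a bare mso_problem for toy capacity matrices
toy_mso <- function(R, tau, lb = rep(0, ncol(R)), ub = rep(1, ncol(R)),
                    n_muscles = ncol(R)) {
  structure(list(R = R, tau = tau, lb = lb, ub = ub,
                 effectors = paste0("e", seq_len(ncol(R))),
                 n_muscles = n_muscles,
                 coords = paste0("c", seq_len(nrow(R)))),
            class = "mso_problem")
}

test_that("zero torque demand yields the zero solution", {
  R <- matrix(c(10, 20, 0, 5, 0, 30), 2, 3)
  sol <- solve_mso_frame(toy_mso(R, c(0, 0)))
  expect_equal(unname(sol$x), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(sol$J, 0, tolerance = 1e-12)
  expect_true(sol$feasible)
})

test_that("two-muscle frame matches the Lagrange closed form and a grid", {
  F1r1 <- 50 * 0.04; F2r2 <- 80 * 0.05
  R <- matrix(c(F1r1, F2r2), 1, 2)
  tau <- 1.5
  sol <- solve_mso_frame(toy_mso(R, tau))
  a_exp <- tau * c(F1r1, F2r2) / (F1r1^2 + F2r2^2)
  expect_equal(unname(sol$x), a_exp, tolerance = 1e-8)
  # brute-force grid oracle at 0.001 resolution
  grid <- seq(0, 1, by = 0.001)
  best <- c(Inf, NA, NA)
  for (a1 in grid) {
    a2 <- (tau - F1r1 * a1) / F2r2
    if (a2 >= 0 && a2 <= 1) {
      J <- a1^2 + a2^2
      if (J < best[1]) best <- c(J, a1, a2)
    }
  }
  expect_lt(max(abs(unname(sol$x) - best[2:3])), 2e-3)
})

test_that("three-effector frames match a brute-force grid oracle", {
  set.seed(21)
  for (rep in 1:3) {
    R <- matrix(runif(3, 5, 40), 1, 3)
    tau <- runif(1, 1, 10)
    sol <- solve_mso_frame(toy_mso(R, tau))
    g <- seq(0, 1, by = 0.001)
    best <- c(Inf, NA, NA, NA)
    for (a1 in g) {
      a3 <- (tau - R[1] * a1 - R[2] * g) / R[3]
      ok <- a3 >= 0 & a3 <= 1
      if (!any(ok)) next
      J <- a1^2 + g[ok]^2 + a3[ok]^2
      i <- which.min(J)
      if (J[i] < best[1]) best <- c(J[i], a1, g[ok][i], a3[ok][i])
    }
    expect_lt(max(abs(unname(sol$x) - best[2:4])), 2e-3)
    expect_lt(max(abs(R %*% sol$x - tau)), 1e-8 * max(1, abs(tau)))
  }
})

test_that("solver agrees with an independent QP implementation", {
  skip_if_not_installed("pracma")
  set.seed(33)
  R <- matrix(runif(10, -30, 30), 2, 5)
  tau <- c(4, -6)
  sol <- solve_mso_frame(toy_mso(R, tau))
  ref <- pracma::quadprog(diag(2, 5), rep(0, 5), Aeq = R, beq = tau,
                          lb = rep(0, 5), ub = rep(1, 5))
  expect_lt(max(abs(unname(sol$x) - ref$xmin)), 1e-6)
})

test_that("a coordinate spanned only by the actuator is served exactly", {
  m <- amputee_model()
  dyn <- osseogait:::build_dynamic_tree(m)
  q0 <- setNames(numeric(dyn$n), dyn$coords)
  tau <- setNames(numeric(dyn$n), dyn$coords)
  tau["pros_knee"] <- 37.5
  pb <- mso_problem(m, q0, q0, tau)
  sol <- solve_mso_frame(pb)
  expect_true(sol$feasible)
  expect_equal(unname(sol$torques["pros_knee"]), 37.5, tolerance = 1e-6)
  # no muscle spans the prosthetic knee: the actuator supplies it all
  expect_equal(sum(abs(pb$R["pros_knee", seq_len(pb$n_muscles)])), 0)
  expect_equal(unname(sol$actuator_controls["pros_knee_act"] * 1e6), 37.5,
               tolerance = 1e-4)
})

test_that("demand with no capable effector is flagged, never silently clipped", {
  R <- matrix(c(10, 0), 2, 1)   # second coordinate has no effector
  sol <- solve_mso_frame(toy_mso(R, c(2, 5)))
  expect_false(sol$feasible)
  expect_gte(sol$violation, 5)
})

test_that("increasing a muscle's strength never increases the optimum J", {
  set.seed(12)
  for (rep in 1:10) {
    R <- matrix(runif(4, 1, 30), 2, 2)
    tau <- as.numeric(R %*% runif(2, 0.1, 0.6))  # guaranteed feasible
    J1 <- solve_mso_frame(toy_mso(R, tau))$J
    R2 <- R
    R2[, 1] <- R2[, 1] * 1.5   # stronger first muscle
    J2 <- solve_mso_frame(toy_mso(R2, tau))$J
    expect_lte(J2, J1 + 1e-9)
  }
})

test_that("mSO on the synthetic amputee trial is feasible at every frame", {
  trial <- amputee_trial()
  id <- amputee_id()
  ms <- run_mso(amputee_model(), trial$reference, id$torques)
  expect_true(all(ms$feasible))
  expect_true(all(ms$activations >= -1e-12 & ms$activations <= 1 + 1e-12))
  # smooth input gives smooth activations
  expect_lt(ms$mean_dactivation, 0.05)
  # the prosthesis actuators carry the prosthetic knee and ankle torques
  expect_gt(max(abs(ms$actuator_torques)), 10)
})

test_that("disabling the intact-side muscles makes hip rows infeasible", {
  m <- amputee_model()
  m$muscles$status[m$muscles$side == "l"] <- "disabled_anchored"
  dyn <- osseogait:::build_dynamic_tree(m)
  q0 <- setNames(numeric(dyn$n), dyn$coords)
  tau <- setNames(numeric(dyn$n), dyn$coords)
  tau["hip_flexion_l"] <- 20
  sol <- solve_mso_frame(mso_problem(m, q0, q0, tau))
  expect_false(sol$feasible)
  expect_gt(sol$violation, 1)
})

test_that("equality residuals on feasible frames are at solver precision", {
  trial <- amputee_trial()
  id <- amputee_id()
  m <- amputee_model()
  dyn <- osseogait:::build_dynamic_tree(m)
  tr <- osseogait:::as_reference_trajectory(trial$reference, dyn$coords)
  for (k in c(1L, 40L, 90L)) {
    pb <- mso_problem(m, tr$q[k, ], tr$qd[k, ],
                      setNames(id$torques[k, dyn$coords], dyn$coords))
    sol <- solve_mso_frame(pb)
    expect_lt(max(abs(pb$R %*% sol$x - pb$tau)),
              1e-8 * max(1, max(abs(pb$tau))))
  }
})
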