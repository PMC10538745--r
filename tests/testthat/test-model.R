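test_that("healthy model has the published joint and muscle arithmetic", {
  m <- build_healthy_model()
  expect_identical(dof_count(m), 23L)
  expect_identical(mtu_count(m), 92L)
  mus <- m$muscles
  expect_equal(sum(mus$side == "r" & mus$group == "leg"), 43L)
  expect_equal(sum(mus$side == "l" & mus$group == "leg"), 43L)
  expect_equal(sum(mus$group == "lumbar" & mus$side == "r"), 3L)
  # left/right rosters are name-for-name mirror images
  expect_setequal(sub("_r$", "", mus$name[mus$side == "r"]),
                  sub("_l$", "", mus$name[mus$side == "l"]))
})

test_that("coordinate locking removes DOFs, is idempotent, rejects unknowns", {
  m <- build_healthy_model()
  locked <- lock_coordinates(m, c("subtalar_angle_r", "mtp_angle_r",
                                  "subtalar_angle_l", "mtp_angle_l"))
  expect_identical(dof_count(locked), 19L)
  again <- lock_coordinates(locked, "subtalar_angle_r")
  expect_identical(dof_count(again), 19L)
  expect_error(lock_coordinates(m, "no_such_coord"), "unknown coordinate")
})

test_that("amputation transform yields the published model structure", {
  am <- amputee_model()
  expect_identical(dof_count(am), 19L)
  expect_identical(mtu_count(am), 76L)
  s <- amputation_summary(am)
  expect_identical(s$n_removed_muscles, 16L)
  expect_identical(s$n_anchored_muscles, 8L)
  expect_identical(s$n_removed_units, 16L)
  # contralateral roster untouched: 43 leg + 3 lumbar units
  mus <- am$muscles
  expect_equal(sum(mus$side == "l" & mus$group == "leg"), 43L)
  expect_equal(sum(mus$side == "l" & mus$group == "lumbar"), 3L)
  # 76 = 46 contralateral + 3 amputated-side lumbar + (43 - 16) leg units
  expect_equal(sum(mus$side == "r" & mus$group == "leg"), 43L - 16L)
  # anchored units produce no force and have no knee moment arm any more
  anch <- mus[mus$status == "disabled_anchored", ]
  expect_true(all(anch$r_knee == 0))
  expect_true(all(anch$side == "r"))
})

test_that("amputation bookkeeping conserves mass and is side-symmetric", {
  healthy <- build_healthy_model()
  am_r <- apply_amputation(healthy, amputation_spec(side = "r"))
  am_l <- apply_amputation(healthy, amputation_spec(side = "l"))
  removed_mass <- with(healthy$segments,
                       sum(mass[name %in% c("femur_r", "tibia_r", "foot_r")]))
  added_mass <- 4.65 + 0.35 + 1.4 + 0.8
  expect_equal(model_mass(am_r),
               model_mass(healthy) - removed_mass + added_mass,
               tolerance = 1e-12)
  # the mirrored transform gives the same counts and total mass
  expect_identical(dof_count(am_l), dof_count(am_r))
  expect_identical(mtu_count(am_l), mtu_count(am_r))
  expect_equal(model_mass(am_l), model_mass(am_r), tolerance = 1e-12)
  expect_setequal(sub("_l$", "", am_l$amputation$removed_units),
                  sub("_r$", "", am_r$amputation$removed_units))
})

test_that("amputation rejects muscle names absent from the model", {
  expect_error(
    apply_amputation(build_healthy_model(),
                     amputation_spec(removed = c("not_a_muscle"))),
    "no removed units|not in model")
})

test_that("removed and anchored lists must be disjoint", {
  expect_error(amputation_spec(removed = c("soleus", "sar"),
                               anchored = c("sar")),
               "disjoint")
})

test_that("welded-body composition sums mass and obeys the parallel axis", {
  femur <- data.frame(mass = 4.65, com_x = 0, com_y = -0.07, izz = 0.02392)
  implant <- data.frame(mass = 0.35, com_x = 0, com_y = -0.133, izz = 0.0013)
  comp <- composite_welded_body(rbind(femur, implant))
  expect_equal(comp$mass, 5.0, tolerance = 1e-12)

  # welding a massless segment is the identity on mass and COM
  zero <- data.frame(mass = 0, com_x = 0.3, com_y = 0.1, izz = 0)
  comp2 <- composite_welded_body(rbind(femur, zero))
  expect_equal(comp2$mass, femur$mass)
  expect_equal(comp2$com, c(femur$com_x, femur$com_y))
  expect_equal(comp2$izz, femur$izz)

  # brute-force point-mass discretization of two offset cuboids
  cuboid <- function(w, h, mass, cx, cy, n = 60) {
    xs <- seq(-w / 2, w / 2, length.out = n)
    ys <- seq(-h / 2, h / 2, length.out = n)
    g <- expand.grid(x = xs + cx, y = ys + cy)
    g$m <- mass / nrow(g)
    g
  }
  a <- cuboid(0.04, 0.30, 2.0, 0, -0.15)
  b <- cuboid(0.03, 0.20, 0.8, 0.05, -0.35)
  pts <- rbind(a, b)
  com_ref <- c(sum(pts$m * pts$x), sum(pts$m * pts$y)) / sum(pts$m)
  izz_ref <- sum(pts$m * ((pts$x - com_ref[1])^2 + (pts$y - com_ref[2])^2))
  izz_part <- function(p) {
    c0 <- c(sum(p$m * p$x), sum(p$m * p$y)) / sum(p$m)
    sum(p$m * ((p$x - c0[1])^2 + (p$y - c0[2])^2))
  }
  segs <- data.frame(mass = c(2.0, 0.8),
                     com_x = c(0, 0.05), com_y = c(-0.15, -0.35),
                     izz = c(izz_part(a), izz_part(b)))
  comp3 <- composite_welded_body(segs)
  expect_equal(comp3$com, com_ref, tolerance = 1e-10)
  expect_equal(comp3$izz, izz_ref, tolerance = 1e-10)
})

test_that("segment inertia invariants hold for packaged and amputee models", {
  for (m in list(build_healthy_model(), amputee_model())) {
    expect_true(all(m$segments$mass >= 0))
    expect_true(all(m$segments$izz >= 0))
  }
})
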