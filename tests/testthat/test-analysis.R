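test_that("gait events land within one frame of the generator schedule", {
  spec <- gait_spec(cycles = 2L)
  trial <- generate_consistent_trial(amputee_model(), spec)
  ev <- detect_gait_events(trial$grf)
  frame <- 1 / spec$rate   # one camera frame
  # right heel strikes at 0 and cycle (t = 0 is already loaded: the first
  # detectable strike is the second one), toe-offs at stance_fraction
  to_r_exp <- spec$stance_fraction * spec$cycle + c(0, spec$cycle)
  for (x in ev$r$toe_offs)
    expect_lt(min(abs(x - to_r_exp)), frame)
  hs_r_exp <- spec$cycle  # second strike
  expect_true(any(abs(ev$r$heel_strikes - hs_r_exp) < frame))
  # left heel strikes half a cycle out of phase
  hs_l_exp <- spec$cycle * c(0.5, 1.5)
  for (x in hs_l_exp)
    expect_true(any(abs(ev$l$heel_strikes - x) < frame))
})

test_that("flat or sub-threshold force gives no events", {
  times <- seq(0, 1, by = 0.01)
  zero <- list(force = cbind(0, numeric(length(times)), 0),
               cop = matrix(0, length(times), 3),
               torque = numeric(length(times)))
  grf0 <- forceplate_series(times, list(r = zero), 100)
  ev <- detect_gait_events(grf0)
  expect_length(ev$r$heel_strikes, 0L)
  weak <- zero; weak$force[, 2] <- 10  # below the 20 N threshold
  evw <- detect_gait_events(forceplate_series(times, list(r = weak), 100))
  expect_length(evw$r$heel_strikes, 0L)
})

test_that("joint power follows its definition and sign convention", {
  expect_equal(joint_power(10, 2, 50), 0.4)
  expect_equal(joint_power(10, -2, 50), -0.4)
  expect_equal(joint_power(-10, 2, 50), -0.4)
})

test_that("cycle energy integrates power consistently", {
  t <- seq(0, 1, by = 1e-3)
  expect_equal(energy_per_cycle(t, sin(2 * pi * t)), 0, tolerance = 1e-10)
  expect_equal(energy_per_cycle(t, rep(1, length(t))), 1, tolerance = 1e-12)
  # trapezoid vs analytic integral of a packaged-style waveform
  p <- 2 * cos(2 * pi * t) + 0.5 * sin(4 * pi * t) + 0.3
  expect_equal(energy_per_cycle(t, p), 0.3, tolerance = 1e-4)
  # integral of power equals the energy computed from its parts
  w <- c(0, 0.6)
  expect_equal(energy_per_cycle(t, p, w),
               0.3 * 0.6 + 2 * sin(2 * pi * 0.6) / (2 * pi) +
                 0.5 * (1 - cos(4 * pi * 0.6)) / (4 * pi),
               tolerance = 1e-4)
})

test_that("amputated-side plantarflexors sum to an identically zero force", {
  m <- amputee_model()
  trial <- amputee_trial()
  id <- amputee_id()
  ms <- shared("mso_run", function()
    run_mso(m, trial$reference, id$torques))
  f_r <- muscle_group_force(m, ms$activations, trial$reference,
                            "plantarflexors", side = "r")
  expect_true(all(f_r == 0))   # every member removed with the limb
  f_l <- muscle_group_force(m, ms$activations, trial$reference,
                            "plantarflexors", side = "l")
  expect_gt(max(f_l), 100)     # contralateral push-off is alive
})

test_that("group forces are permutation-invariant and reduce to one muscle", {
  m <- amputee_model()
  trial <- amputee_trial()
  id <- amputee_id()
  ms <- shared("mso_run", function()
    run_mso(m, trial$reference, id$torques))
  g <- c("psoas", "iliacus", "pect")
  f1 <- muscle_group_force(m, ms$activations, trial$reference, g, side = "l")
  f2 <- muscle_group_force(m, ms$activations, trial$reference, rev(g),
                           side = "l")
  expect_equal(f1, f2, tolerance = 1e-12)
  fp <- muscle_group_force(m, ms$activations, trial$reference, "psoas",
                           side = "l")
  fi <- muscle_group_force(m, ms$activations, trial$reference, "iliacus",
                           side = "l")
  fc <- muscle_group_force(m, ms$activations, trial$reference,
                           c("psoas", "iliacus"), side = "l")
  expect_equal(fc, fp + fi, tolerance = 1e-9)
})

test_that("flexor and extensor rosters of a joint never overlap", {
  g <- muscle_groups()
  expect_length(intersect(g$hip_flexors, g$hip_extensors), 0L)
  expect_length(intersect(g$knee_flexors, g$knee_extensors), 0L)
  expect_length(intersect(g$plantarflexors, g$dorsiflexors), 0L)
})

test_that("cycle normalization keeps 101 points and preserves integrals", {
  t <- seq(0, 2.5, by = 0.001)
  y <- sin(2 * pi * t / 1.25) + 0.2
  gc <- to_gait_cycle(t, y, heel_strikes = c(0, 1.25, 2.5))
  expect_length(gc$mean, 101L)
  expect_equal(dim(gc$cycles), c(2L, 101L))
  # integral over the normalized cycle (in cycle units) matches the signal
  int_norm <- mean(gc$mean[-101])  # 0.2 for a zero-mean sinusoid + offset
  expect_equal(int_norm, 0.2, tolerance = 1e-3)
  expect_lt(max(gc$sd), 1e-6)      # identical cycles
  # single heel strike with an explicit duration works
  gc1 <- to_gait_cycle(t, y, heel_strikes = 0, cycle = 1.25)
  expect_equal(gc1$mean, gc$cycles[1, ], tolerance = 1e-9)
})
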