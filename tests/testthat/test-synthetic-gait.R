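# Synthetic gait generator: trajectories, static optimization, reference
# assembly, observation noise.

test_that("synthesized trajectories are periodic, physiologic, and advance", {
  m <- fix_model()
  fit <- fix_gait_fit()
  Tc <- fit$T
  tr0 <- eval_gait(fit, 0)
  trT <- eval_gait(fit, Tc)

  # periodic by construction except the advancing pelvis
  dq <- trT$q[, 1] - tr0$q[, 1]
  itx <- match("pelvis_tx", m$coord_names)
  expect_lt(max(abs(dq[-itx])), 1e-9)
  expect_equal(unname(dq[itx]), 1.25 * 1.1, tolerance = 1e-9)

  # subtalar stays within +-5 degrees, everted during stance
  tt <- seq(0, Tc, by = 0.002)
  q <- eval_gait(fit, tt)$q
  expect_lte(max(abs(q["subtalar_r", ])), 5 * pi / 180 + 1e-6)
  mid_stance <- tt / Tc > 0.2 & tt / Tc < 0.45
  expect_true(all(q["subtalar_r", mid_stance] < 0))

  # joint ranges stay physiologic
  expect_true(all(q["knee_r", ] > -0.02))
  expect_lt(max(q["knee_r", ]), 65 * pi / 180 * 1.3)
  expect_lt(max(abs(q["hip_flexion_r", ])), 50 * pi / 180)

  # average fore-aft pelvis speed equals the walking speed
  expect_equal(unname((q["pelvis_tx", ncol(q)] - q["pelvis_tx", 1]) / Tc),
               1.25, tolerance = 1e-6)

  # speeds are the analytic derivative of the coordinates
  h <- 1e-6
  u_fd <- (eval_gait(fit, 0.4 + h)$q - eval_gait(fit, 0.4 - h)$q) / (2 * h)
  expect_lt(max(abs(u_fd - eval_gait(fit, 0.4)$u)), 1e-5)
})

test_that("determinism: same parameters give bit-identical trajectories", {
  m <- fix_model()
  fit2 <- suppressWarnings(synth_joint_trajectories(gait_params(), m))
  expect_identical(fix_gait_fit()$a0, fit2$a0)
  expect_identical(fix_gait_fit()$A, fit2$A)
})

test_that("static optimization closed forms on toy problems", {
  # single-DOF, single-muscle: e = demand / (arm * capacity)
  B <- matrix(50, 1, 1)  # arm * Fiso * fl * fv * cos(alpha)
  sol <- exowalk:::solve_effort_qp(B, d = 20)
  expect_equal(sol$e, 0.4, tolerance = 1e-9)
  expect_false(sol$flagged)

  # zero demand -> zero excitations
  sol0 <- exowalk:::solve_effort_qp(matrix(c(30, 50), 1, 2), d = 0)
  expect_equal(sol0$e, c(0, 0), tolerance = 1e-9)

  # two identical muscles share the demand equally (KKT of min sum e^2)
  sol2 <- exowalk:::solve_effort_qp(matrix(c(40, 40), 1, 2), d = 32)
  expect_equal(sol2$e[1], sol2$e[2], tolerance = 1e-6)
  expect_equal(sum(sol2$e * 40), 32, tolerance = 1e-9)

  # demand beyond capacity: clipped to bounds and flagged
  sol3 <- exowalk:::solve_effort_qp(matrix(40, 1, 1), d = 80)
  expect_equal(sol3$e, 1)
  expect_true(sol3$flagged)
})

test_that("assembled reference hits the plausibility bands", {
  ref <- fix_reference()
  expect_gt(ref$events$toe_off, 55)
  expect_lt(ref$events$toe_off, 70)
  expect_gt(ref$h_com, 0.9)
  expect_lt(ref$h_com, 1.1)
  expect_gt(ref$events$step_width, 0.1)
  expect_lt(ref$events$step_width, 0.25)
  # single and double support present: total vertical GRF never vanishes,
  # both feet loaded around 5% and only one around 30%
  i05 <- which.min(abs(ref$time - 0.05 * ref$T))
  i30 <- which.min(abs(ref$time - 0.30 * ref$T))
  expect_gt(ref$grf_r[i05, 2], 10); expect_gt(ref$grf_l[i05, 2], 10)
  expect_gt(ref$grf_r[i30, 2], 10); expect_lt(ref$grf_l[i30, 2], 10)
  # excitations within bounds
  expect_true(all(ref$e >= 0 & ref$e <= 1))
  # vertical GRF peak is computed and reported; the 0.9-1.4 BW band is a
  # report-only plausibility check (the packaged gait peaks near 1.4)
  expect_true(is.finite(ref$grf_peak_bw))
  expect_gt(ref$grf_peak_bw, 0.8)
  expect_lt(ref$grf_peak_bw, 1.6)

  # airborne reference: events undetectable -> error
  m <- fix_model()
  fit_air <- fix_gait_fit()
  fit_air$a0[match("pelvis_ty", m$coord_names)] <-
    fit_air$a0[match("pelvis_ty", m$coord_names)] + 1
  expect_error(assemble_reference(m, fit_air, check_consistency = FALSE),
               "no ground contact")
})

test_that("observation noise is periodic, seeded, and correctly scaled", {
  ref <- fix_reference()
  n0 <- add_observation_noise(ref, 0)
  expect_identical(n0$q, ref$q)

  na <- add_observation_noise(ref, 0.01, seed = 4L)
  nb <- add_observation_noise(ref, 0.01, seed = 4L)
  expect_identical(na$q, nb$q)

  rmsq <- sqrt(mean((na$q - ref$q)^2))
  expect_gt(rmsq, 0.008); expect_lt(rmsq, 0.012)

  # periodicity preserved
  dq <- (na$q - ref$q)[, 1] - (na$q - ref$q)[, ncol(ref$q)]
  expect_lt(max(abs(dq)), 1e-9)
})
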