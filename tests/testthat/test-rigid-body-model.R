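# Rigid-body model: construction, dynamics, passive forces, COM, WBAM.

test_that("default model has 23 DOF, correct mass, and validates its spec", {
  m <- fix_model()
  expect_equal(m$ndof, 23L)  # 6 + 3 + 2*(3+1+1+1+1)
  expect_equal(m$total_mass, 72.4, tolerance = 1e-12)
  expect_equal(m$n_muscles, 24L)
  expect_equal(length(m$sphere_foot), 12L)

  # two root (free) joints -> error
  spec <- default_model_spec()
  spec$joints[[10]]$parent <- NA
  expect_error(build_reduced_model(spec), "exactly one free")

  # broken tree / unknown parent
  spec2 <- default_model_spec()
  spec2$joints[[5]]$parent <- "nope"
  expect_error(build_reduced_model(spec2), "unknown parent")

  # non-unit axis
  spec3 <- default_model_spec()
  spec3$joints[[10]]$axis <- c(0, 0, 2)
  expect_error(build_reduced_model(spec3), "unit-norm")
})

test_that("forward dynamics: free fall, pendulum closed form, energy", {
  m <- fix_model()
  q <- numeric(23); q[2] <- 2.0
  st <- kinematic_state(m, q)
  ud <- forward_dynamics(m, st)
  expect_equal(ud[2], -9.81, tolerance = 1e-9)
  com <- com_kinematics(m, st, ud)
  expect_equal(com$acc, c(0, -9.81, 0), tolerance = 1e-8)

  # single pendulum small angle: udot = -m g lc sin(q) / (I + m lc^2)
  toy <- toy_pendulum(m = 2, lc = 0.5, Icom = 0.1)
  st2 <- kinematic_state(toy, 0.05)
  expect_equal(forward_dynamics(toy, st2),
               -2 * 9.81 * 0.5 * sin(0.05) / (0.1 + 2 * 0.25),
               tolerance = 1e-10)

  # conservative swing: energy drift < 1e-4 J over 1 s at accuracy 1e-6
  tr <- exowalk:::cpp_integrate_window(toy$ptr, c(1.0, 0), 0, 1,
                                       zero_ctrl(toy), 1L, no_exo(), 1e-6,
                                       1e-6, 1e-3, 100000L)
  e0 <- model_energy(toy, kinematic_state(toy, tr$Y[1, 1], tr$Y[2, 1]))
  nlast <- ncol(tr$Y)
  e1 <- model_energy(toy, kinematic_state(toy, tr$Y[1, nlast], tr$Y[2, nlast]))
  expect_lt(abs((e1$ke + e1$pe) - (e0$ke + e0$pe)), 1e-4)
})

test_that("energy balance with damping matches non-conservative power", {
  # d/dt(KE+PE) = damper power, checked over a short window
  toy <- toy_pendulum(damping = 0.3)
  tr <- exowalk:::cpp_integrate_window(toy$ptr, c(1.2, 0), 0, 0.1,
                                       zero_ctrl(toy), 1L, no_exo(), 1e-6,
                                       1e-6, 1e-4, 100000L)
  Y <- tr$Y
  en <- vapply(seq_len(ncol(Y)), function(i) {
    e <- model_energy(toy, kinematic_state(toy, Y[1, i], Y[2, i]))
    e$ke + e$pe
  }, 0)
  # work done by damper = integral of -b u^2
  u <- Y[2, ]
  dt <- diff(tr$time)
  work <- -0.3 * sum(0.5 * (u[-1]^2 + u[-length(u)]^2) * dt)
  dE <- en[length(en)] - en[1]
  expect_lt(abs(dE - work), 1e-3 * max(abs(dE), abs(work)))
})

test_that("mass matrix is symmetric positive definite at random states", {
  m <- fix_model()
  set.seed(42)
  for (i in 1:100) {
    q <- runif(23, -0.3, 0.3); q[2] <- 1.0
    M <- mass_matrix(m, q)
    expect_lt(max(abs(M - t(M))), 1e-9)
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("internal torque pairs leave the COM untouched (Newton's third law)", {
  m <- fix_model()
  q <- numeric(23); q[2] <- 2.0  # airborne
  st <- kinematic_state(m, q, u = runif(23, -0.1, 0.1))
  dev <- exo_device("PF+EV")
  pairs <- device_body_torques(dev, 7.24, m, st)
  tau <- numeric(23)
  for (p in pairs) {
    tau <- tau + generalized_from_wrench(m, st, p$child, torque = p$child_torque)
    tau <- tau + generalized_from_wrench(m, st, p$parent, torque = p$parent_torque)
    expect_equal(p$child_torque + p$parent_torque, c(0, 0, 0))
  }
  ud0 <- forward_dynamics(m, st)
  ud1 <- forward_dynamics(m, st, tau)
  a0 <- com_kinematics(m, st, ud0)$acc
  a1 <- com_kinematics(m, st, ud1)$acc
  expect_lt(max(abs(a1 - a0)) / 9.81, 1e-9)
})

test_that("passive forces match the published spring/damper constants", {
  m <- fix_model()
  q <- numeric(23); u <- numeric(23)
  q[coord_idx <- match("lumbar_extension", m$coord_names)] <- 0.1
  P <- passive_generalized_forces(m, kinematic_state(m, q, u))
  expect_equal(P["lumbar_extension", "spring"], -1.0 * 72.4 * 0.1,
               tolerance = 1e-9)

  q <- numeric(23); u[match("ankle_r", m$coord_names)] <- 1
  P <- passive_generalized_forces(m, kinematic_state(m, q, u))
  # 2 N m s/rad ankle damping plus the bushing damping
  pp <- default_passive_params()
  expect_equal(P["ankle_r", "damper"],
               -(pp$ankle_damping + pp$bushing_damping), tolerance = 1e-9)
  expect_lte(P["ankle_r", "damper"], -2.0)

  q <- numeric(23); u <- numeric(23)
  q[match("mtp_r", m$coord_names)] <- 0.2
  P <- passive_generalized_forces(m, kinematic_state(m, q, u))
  expect_equal(P["mtp_r", "spring"], -25.0 * 0.2, tolerance = 1e-9)

  # neutral pose, zero speeds: passive forces vanish (guards are exactly
  # zero inside their engagement range)
  P0 <- passive_generalized_forces(m, kinematic_state(m, numeric(23)))
  expect_lt(max(abs(P0[, "total"])), 1e-6)
})

test_that("COM and WBAM definitions", {
  # two equal masses at y=0 and y=1 via a free body plus geometry: use the
  # toy free body with COM checks instead
  m <- fix_model()
  st <- kinematic_state(m, c(0, 2, numeric(21)))
  expect_equal(whole_body_angular_momentum(m, st), c(0, 0, 0),
               tolerance = 1e-12)

  # single rigid body spinning about its COM: H = I w
  fb <- toy_free_body(m = 5, Idiag = c(0.2, 0.3, 0.4))
  u <- c(0, 0, 0, 1.2, 0, 0)  # spin about z
  st2 <- kinematic_state(fb, numeric(6), u)
  expect_equal(whole_body_angular_momentum(fb, st2), c(0, 0, 0.4 * 1.2),
               tolerance = 1e-10)

  # WBAM conserved in flight (gravity has no moment about the COM)
  u0 <- c(0.3, 1, 0, 2.0, 1.0, 0.5)
  tr <- exowalk:::cpp_integrate_window(fb$ptr, c(c(0, 2, 0, 0, 0, 0), u0), 0,
                                       0.1, zero_ctrl(fb), 1L, no_exo(),
                                       1e-6, 1e-6, 1e-3, 100000L)
  nlast <- ncol(tr$Y)
  H0 <- whole_body_angular_momentum(fb, kinematic_state(fb, tr$Y[1:6, 1],
                                                        tr$Y[7:12, 1]))
  H1 <- whole_body_angular_momentum(fb, kinematic_state(fb, tr$Y[1:6, nlast],
                                                        tr$Y[7:12, nlast]))
  expect_lt(max(abs(H1 - H0)), 1e-6)
})

test_that("range violations are reported, not clamped", {
  m <- fix_model()
  q <- numeric(23); q[match("knee_r", m$coord_names)] <- 3.0
  st <- kinematic_state(m, q)
  expect_true("knee_r" %in% attr(st, "range_violations"))
  expect_equal(st$q[match("knee_r", m$coord_names)], 3.0)
})
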