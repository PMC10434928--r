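# Hill-type muscle mechanics: activation dynamics, characteristic curves,
# tendon-force state and joint-moment production.

test_that("activation dynamics: fixed point, sign, and step-response scale", {
  expect_equal(activation_dynamics(0.5, 0.5), 0)
  expect_gt(activation_dynamics(1, 0), 0)
  # activation is faster than deactivation
  expect_gt(abs(activation_dynamics(1, 0.2)), abs(activation_dynamics(0, 0.8)))

  # time to 63% of a 0 -> 1 step is close to tau_act
  a <- 0; dt <- 1e-4; t63 <- NA
  for (i in 1:4000) {
    a <- a + dt * activation_dynamics(1, a)
    if (is.na(t63) && a >= 0.63) t63 <- i * dt
  }
  expect_lt(abs(t63 - 0.015) / 0.015, 0.10)
})

test_that("characteristic curves have the required shape", {
  cc <- characteristic_curves(1, 0)
  expect_equal(cc$f_active_length, 1, tolerance = 1e-3)
  expect_equal(cc$f_velocity, 1, tolerance = 1e-6)
  # peak of the active curve is at normalized length 1
  grid <- seq(0.5, 1.6, by = 0.001)
  fal <- characteristic_curves(grid)$f_active_length
  expect_equal(grid[which.max(fal)], 1, tolerance = 2e-3)
  expect_true(all(fal >= 0 & fal <= 1 + 1e-12))

  # force-velocity: near zero at maximal shortening, plateau lengthening
  expect_lt(characteristic_curves(1, -1)$f_velocity, 0.05)
  expect_gt(characteristic_curves(1, -1)$f_velocity, 0)
  expect_gt(characteristic_curves(1, 1)$f_velocity, 1)

  # passive curve: nondecreasing, strictly greater at 1.6 than at 1.0
  fpe <- characteristic_curves(grid)$f_passive_length
  expect_true(all(diff(fpe) >= -1e-12))
  expect_gt(characteristic_curves(1.6)$f_passive_length,
            characteristic_curves(1.0)$f_passive_length)
  expect_true(all(fpe >= 0))
})

test_that("tendon curve: slack, normalization at eps0, convexity, C1", {
  expect_lte(abs(tendon_force_from_length(1.0)), 0.01)
  expect_equal(tendon_force_from_length(1.10, eps0 = 0.10), 1, tolerance = 1e-6)
  # strictly increasing above slack; convex on [1, 1+eps0]
  g <- seq(1, 1.10, length.out = 200)
  f <- tendon_force_from_length(g)
  expect_true(all(diff(f) > 0))
  expect_true(all(diff(diff(f)) > 0))
  # C1 across the slack point: numeric derivative jump < 1e-3
  h <- 1e-5
  dl <- (tendon_force_from_length(1 + h) - tendon_force_from_length(1)) / h
  dr <- (tendon_force_from_length(1) - tendon_force_from_length(1 - h)) / h
  expect_lt(abs(dl - dr), 1e-3 * max(1, abs(dl)))
})

test_that("tendon-force state derivative: equilibrium, stability, rigid error", {
  mu <- soleus_params()
  mu$eps0 <- 0.10
  # constructed isometric equilibrium -> derivative ~ 0
  a <- 0.5
  lmt <- mu$lts * 1.03 + sqrt((0.95 * mu$lopt)^2 - (mu$lopt * sin(mu$alpha))^2)
  ft_eq <- exowalk:::cpp_tendon_equilibrium(mu$fiso, mu$lopt, mu$lts,
                                            mu$alpha, mu$eps0, a, lmt)
  out <- tendon_force_state_derivative(mu, a, ft_eq, lmt, 0)
  expect_lt(abs(out$dft), 1e-6)

  # above equilibrium at fixed lmt -> force decreases (stable equilibrium)
  out_hi <- tendon_force_state_derivative(mu, a, ft_eq + 0.05, lmt, 0)
  expect_lt(out_hi$dft, 0)
  out_lo <- tendon_force_state_derivative(mu, a, max(ft_eq - 0.05, 1e-3), lmt, 0)
  expect_gt(out_lo$dft, 0)

  # rigid-tendon muscle is rejected
  mu_r <- soleus_params(); mu_r$eps0 <- NA
  expect_error(tendon_force_state_derivative(mu_r, 0.5, 0.5, lmt, 0),
               "compliant")
})

test_that("tendon-state derivative sign agrees with an explicit fiber ODE", {
  # independent oracle: integrate the fiber-length ODE (explicit velocity
  # from the same equilibrium inversion) and compare the implied tendon
  # force change over a short isometric hold
  mu <- soleus_params(); mu$eps0 <- 0.10
  a <- 0.6
  lmt <- mu$lts * 1.02 + sqrt((0.9 * mu$lopt)^2 - (mu$lopt * sin(mu$alpha))^2)
  ft <- exowalk:::cpp_tendon_equilibrium(mu$fiso, mu$lopt, mu$lts, mu$alpha,
                                         mu$eps0, a, lmt) + 0.1
  dt <- 1e-4
  ftt <- ft
  for (i in 1:50)
    ftt <- ftt + dt * tendon_force_state_derivative(mu, a, ftt, lmt, 0)$dft
  # relaxes monotonically toward the equilibrium from above
  expect_lt(ftt, ft)
  expect_gt(ftt, ft - 0.1 - 0.05)
})

test_that("muscle generalized forces: zero activation, toy moment, FD arms", {
  m <- fix_model()
  # loaded mid-stance anchoring posture: fibers at 0.92 of optimal length,
  # well below passive engagement
  qref <- numeric(23)
  names(qref) <- m$coord_names
  for (side in c("r", "l")) {
    qref[paste0("hip_flexion_", side)] <- 0.35
    qref[paste0("knee_", side)] <- 0.25
    qref[paste0("ankle_", side)] <- 0.08
    qref[paste0("subtalar_", side)] <- -0.04
  }
  qref["pelvis_ty"] <- 2  # airborne: no contact in this check
  st <- kinematic_state(m, qref)
  out <- muscle_generalized_forces(m, st)
  expect_lt(max(abs(out$tau)), 0.5)

  # constant-arm toy: F_T = 1000 N at arm 0.05 m -> 50 N m
  flat <- toy_pendulum()$flat
  flat$muscles <- list(list(name = "mus", fiso = 2000, lopt = 0.1, lts = 0.2,
                            alpha = 0, eps0 = 0.1, tact = 0.015,
                            tdeact = 0.06, vmax = 10, L0 = 0.3,
                            path = rbind(0L, -0.05, 0)))
  toy <- exowalk:::build_flat_model(flat)
  st2 <- kinematic_state(toy, 0)
  out2 <- muscle_generalized_forces(toy, st2, activations = 0.5,
                                    ft_tilde = 1000 / 2000)
  expect_equal(unname(out2$FT), 1000, tolerance = 1e-9)
  expect_equal(unname(out2$tau), 0.05 * 1000, tolerance = 1e-9)

  # moment arms match central finite differences of lmt(q)
  set.seed(7)
  q <- runif(23, -0.2, 0.2)
  st3 <- kinematic_state(m, q)
  g <- muscle_geometry(m, st3)
  h <- 1e-6
  for (j in match(c("knee_r", "ankle_r", "subtalar_l"), m$coord_names)) {
    qp <- q; qp[j] <- qp[j] + h
    qm <- q; qm[j] <- qm[j] - h
    lp <- muscle_geometry(m, kinematic_state(m, qp))$lmt
    lm <- muscle_geometry(m, kinematic_state(m, qm))$lmt
    fd_arm <- -(lp - lm) / (2 * h)
    expect_lt(max(abs(fd_arm - g$arms[, j])), 1e-6)
  }
})

test_that("rigid-tendon limit and isometric maximal force", {
  # a very stiff tendon reproduces the rigid-tendon force within 1%
  mu <- soleus_params()
  set.seed(3)
  for (i in 1:10) {
    a <- runif(1, 0.2, 1)
    ltil <- runif(1, 0.8, 1.1)
    h <- mu$lopt * sin(mu$alpha)
    lmt <- mu$lts + sqrt((ltil * mu$lopt)^2 - h^2)
    # rigid force
    proj <- lmt - mu$lts
    lM <- sqrt(proj^2 + h^2); cosa <- proj / lM
    f_rigid <- mu$fiso * (a * characteristic_curves(lM / mu$lopt, 0)$f_active_length +
                            characteristic_curves(lM / mu$lopt)$f_passive_length) * cosa
    ft_stiff <- exowalk:::cpp_tendon_equilibrium(mu$fiso, mu$lopt, mu$lts,
                                                 mu$alpha, 1e-4, a, lmt)
    expect_lt(abs(ft_stiff * mu$fiso - f_rigid) / f_rigid, 0.01)
  }

  # a = 1, optimal fiber, zero velocity, rigid tendon, no pennation
  ft1 <- exowalk:::cpp_tendon_equilibrium(1000, 0.1, 0.2, 0, 1e-4, 1,
                                          0.2 * 1.0001 + 0.1)
  expect_lt(abs(ft1 * 1000 - 1000) / 1000, 0.005)
})

test_that("activation stays within [0,1] for arbitrary excitations", {
  set.seed(11)
  for (rep in 1:100) {
    a <- runif(1)
    e <- runif(200)
    dt <- 5e-3
    for (i in seq_along(e)) {
      a <- a + dt * activation_dynamics(e[i], a)
      expect_true(a >= -1e-6 && a <= 1 + 1e-6)
    }
  }
})
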