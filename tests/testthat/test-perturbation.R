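# Perturbation engine: windows, initial states, torque-driven variant,
# integration, condition runs.

test_that("simulation window arithmetic", {
  w <- sim_window(40, 1.1)
  expect_equal(w$onset_pct, 30); expect_equal(w$end_pct, 45)
  expect_equal(w$end_pct - w$onset_pct, 15)
  expect_equal(w$t_peak, 0.44, tolerance = 1e-12)
  expect_error(sim_window(5, 1.1))
})

test_that("initial state interpolation", {
  m <- fix_model()
  ref <- fix_reference()
  # at a stored node: exact
  y <- initial_state_at(m, ref, 10)
  i <- which.min(abs(ref$time - 0.11))
  expect_equal(unname(y[1:23]), unname(ref$q[, i]), tolerance = 1e-9)
  expect_equal(unname(y[47:70]), unname(ref$a[, i]), tolerance = 1e-9)
  # earliest grid condition (peak 20 -> onset 10) is valid
  expect_length(initial_state_at(m, ref, 10), 2 * 23 + 24 + m$n_ft)
  # between nodes: within neighbor bounds for the muscle states (linear)
  y2 <- initial_state_at(m, ref, 10.04)
  a2 <- y2[47:70]
  lo <- pmin(ref$a[, i], ref$a[, i + 1]); hi <- pmax(ref$a[, i], ref$a[, i + 1])
  expect_true(all(a2 >= lo - 1e-12 & a2 <= hi + 1e-12))
  # missing muscle states rejected
  ref2 <- ref; ref2$a <- NULL
  expect_error(initial_state_at(m, ref2, 10), "muscle states")
})

test_that("torque-driven variant matches muscle-driven at the reference", {
  m <- fix_model()
  ref <- fix_reference()
  ctrl_td <- make_torque_driven(m, ref)
  # prescribed moments equal the muscle-generated moments along the
  # reference by construction
  i <- which.min(abs(ref$time - 0.35))
  st <- kinematic_state(m, ref$q[, i], ref$u[, i])
  tau_m <- muscle_generalized_forces(m, st, ref$a[, i], ref$ft[, i])$tau
  expect_equal(unname(ctrl_td$pm[i, ]), unname(tau_m), tolerance = 1e-9)

  # integrating both modes from the same state for 1 ms with zero exo
  # torque: states stay within 1e-5
  y0m <- initial_state_at(m, ref, 30, "muscle_driven")
  y0t <- initial_state_at(m, ref, 30, "torque_driven")
  t0 <- 0.30 * ref$T
  trm <- integrate_window(m, y0m, t0, t0 + 0.001, reference_controls(ref),
                          "muscle_driven")
  trt <- integrate_window(m, y0t, t0, t0 + 0.001, ctrl_td, "torque_driven")
  expect_lt(max(abs(trm$q[, ncol(trm$q)] - trt$q[, ncol(trt$q)])), 1e-5)
})

test_that("integrator: linear ODE, zero-length window, accuracy", {
  # slider with damper: u' = -u, closed form e^(-t)
  toy <- toy_damped_slider(m = 1, b = 1)
  ctrl <- zero_ctrl(toy)
  tr <- exowalk:::cpp_integrate_window(toy$ptr, c(0, 1), 0, 1, ctrl, 1L,
                                       no_exo(), 1e-8, 1e-8, 1e-2, 100000L)
  expect_lt(abs(tr$Y[2, ncol(tr$Y)] - exp(-1)) / exp(-1), 1e-6)

  # zero-length window: trajectory = initial state only
  tr0 <- exowalk:::cpp_integrate_window(toy$ptr, c(0.3, -0.2), 0.5, 0.5, ctrl,
                                        1L, no_exo(), 1e-6, 1e-6, 1e-3, 1000L)
  expect_equal(ncol(tr0$Y), 1)
  expect_equal(tr0$Y[, 1], c(0.3, -0.2))

  # tightening accuracy 1e-6 -> 1e-8 barely moves the endpoint COM
  m <- fix_model(); ref <- fix_reference()
  y0 <- initial_state_at(m, ref, 30)
  t0 <- 0.30 * ref$T; t1 <- t0 + 0.05
  ctrlw <- reference_controls(ref)
  tra <- integrate_window(m, y0, t0, t1, ctrlw, accuracy = 1e-6)
  trb <- integrate_window(m, y0, t0, t1, ctrlw, accuracy = 1e-8)
  na <- nrow(tra$com_pos)
  expect_lt(max(abs(tra$com_pos[na, ] - trb$com_pos[nrow(trb$com_pos), ])),
            1e-5)
})

test_that("run_condition: zero magnitude, determinism, baseline sharing", {
  m <- fix_model(); ref <- fix_reference()
  pair0 <- run_condition(m, ref, "PF", 40, "muscle_driven", peak_torque = 0)
  expect_identical(pair0$exo$Y, pair0$baseline$Y)

  cache <- fix_cache()
  p1 <- run_condition(m, ref, "EV", 40, "muscle_driven", cache = cache)
  p2 <- run_condition(m, ref, "EV", 40, "muscle_driven", cache = cache)
  expect_identical(p1$exo$Y, p2$exo$Y)  # cached, hence byte-identical
  # fresh recomputation is also byte-identical (deterministic integration)
  p3 <- run_condition(m, ref, "EV", 40, "muscle_driven")
  expect_identical(p1$exo$Y, p3$exo$Y)
  # exo and baseline share the initial state
  expect_equal(p1$exo$Y[, 1], p1$baseline$Y[, 1])
})

test_that("baseline cancellation is linear in small magnitudes", {
  m <- fix_model(); ref <- fix_reference()
  cache <- fix_cache()
  mags <- c(0.0125, 0.025, 0.05)
  dn <- vapply(mags, function(mg) {
    pair <- run_condition(m, ref, "PF", 40, "muscle_driven",
                          peak_torque = mg, cache = cache)
    sqrt(sum((pair$exo$Y[, ncol(pair$exo$Y)] -
                pair$baseline$Y[, ncol(pair$baseline$Y)])[1:23]^2))
  }, 0)
  # slope is finite and approximately constant (ratios near magnitude ratios)
  expect_lt(abs(dn[2] / dn[1] - 2), 0.4)
  expect_lt(abs(dn[3] / dn[2] - 2), 0.4)
})

test_that("flight phase: exoskeleton torque pairs cannot accelerate the COM", {
  # airborne model, exo torque at full magnitude: COM acceleration equals
  # gravity to 1e-9 relative
  m <- fix_model(); ref <- fix_reference()
  y0 <- initial_state_at(m, ref, 30)
  y0[2] <- y0[2] + 1  # lift above ground: no contact
  w <- sim_window(40, ref$T)
  exo <- exowalk:::exo_actuation(m, exo_device("PF+INV"), w, 0.1, ref$mass)
  out <- exowalk:::cpp_rhs(m$ptr, w$t_peak, y0, reference_controls(ref), 0L, exo)
  # remove the residual-actuator pelvis forces (external by construction)
  res <- exowalk:::.obs_at(ref, "res", w$t_peak)
  acc_expect <- c(res[1], res[2] - ref$mass * 9.81, res[3]) / ref$mass
  expect_lt(max(abs(out$com_acc - acc_expect)) / 9.81, 1e-9)
})
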