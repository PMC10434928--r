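# Exoskeleton devices: torque profile, body-torque pairs, condition grid.

test_that("four-parameter torque profile", {
  p <- torque_profile_params(peak_time = 40)
  expect_equal(p$onset, 30); expect_equal(p$end, 45)
  expect_equal(p$end - p$onset, 15)  # window = rise + fall

  expect_equal(profile_value(p$onset, p), 0)
  expect_equal(profile_value(p$end, p), 0)
  expect_equal(profile_value(40, p), 0.1)
  # falling cubic midpoint is exactly half the peak
  expect_equal(profile_value(40 + 2.5, p), 0.05, tolerance = 1e-12)
  expect_true(all(profile_value(seq(0, 100, 0.1), p) >= 0))

  # C1: numeric slope is continuous at onset, peak, end
  h <- 1e-6
  for (tq in c(p$onset, 40, p$end)) {
    sl <- (profile_value(tq + h, p) - profile_value(tq - h, p)) / (2 * h)
    expect_lt(abs(sl), 1e-3)
  }

  # integral matches the closed form peak*(rise+fall)/2 (cubic smoothstep)
  tq <- seq(0, 100, length.out = 200001)
  quad <- sum(profile_value(tq, p)) * (tq[2] - tq[1])
  expect_equal(quad, 0.1 * (10 + 5) / 2, tolerance = 1e-6)

  # linearity: doubling the peak doubles the profile pointwise
  p2 <- torque_profile_params(40, peak_torque = 0.2)
  expect_equal(profile_value(tq[1:1000], p2), 2 * profile_value(tq[1:1000], p),
               tolerance = 1e-12)

  # invalid windows rejected
  expect_error(torque_profile_params(5))           # onset < 0
  expect_error(torque_profile_params(98))          # end > 100
})

test_that("device definitions and body torque pairs", {
  m <- fix_model()
  st <- kinematic_state(m, numeric(23))
  pf <- device_body_torques(exo_device("PF"), 7.24, m, st)
  expect_length(pf, 1)
  expect_equal(pf[[1]]$child, "talus_r")
  expect_equal(pf[[1]]$parent, "tibia_r")
  expect_equal(pf[[1]]$child_torque + pf[[1]]$parent_torque, c(0, 0, 0))
  expect_equal(sqrt(sum(pf[[1]]$child_torque^2)), 7.24, tolerance = 1e-12)

  both <- device_body_torques(exo_device("PF+EV"), 5, m, st)
  expect_length(both, 2)
  expect_equal(both[[2]]$child, "calcn_r")
  expect_equal(both[[2]]$parent, "talus_r")

  z <- device_body_torques(exo_device("INV"), 0, m, st)
  expect_equal(z[[1]]$child_torque, c(0, 0, 0))

  expect_error(exo_device("DORSI"))
})

test_that("condition grid enumeration", {
  dev_only <- enumerate_conditions(include_modes = "muscle_driven",
                                   peak_times = 40)
  expect_equal(nrow(dev_only), 5)

  one_dev <- enumerate_conditions(include_modes = "muscle_driven",
                                  devices = "PF")
  expect_equal(nrow(one_dev), 9)
  expect_equal(one_dev$peak_time, seq(20, 60, 5))

  full <- enumerate_conditions()
  expect_equal(nrow(full), 90)
  # deterministic ordering: device-major, then peak time, then mode
  expect_equal(full$device[1:18], rep("PF", 18))
  expect_equal(full$peak_time[1:4], c(20, 20, 25, 25))
  expect_equal(full$mode[1:2], c("muscle_driven", "torque_driven"))
  expect_error(enumerate_conditions(include_modes = "psychic"))
})
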