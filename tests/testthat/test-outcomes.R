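# Outcome battery: deltas, normalization, power, linearity, summaries.

fake_pair <- function(dv = c(0, 0, 0), exo_torque = NULL, u_ankle = NULL,
                      T = 1.1, peak_time = 40, device = "PF",
                      peak_torque = 0.1) {
  w <- sim_window(peak_time, T)
  tt <- seq(w$t_on, w$t_end, by = 1e-3)
  n <- length(tt)
  mk <- function(v) matrix(rep(v, each = n), n, 3)
  base <- list(time = tt, com_acc = mk(c(0, 0, 0)), com_vel = mk(c(1.25, 0, 0)),
               com_pos = mk(c(0, 1, 0)), wbam = mk(c(0, 0, 0)),
               cop_r = mk(c(0.1, 0, 0.08)), cop_r_defined = rep(TRUE, n),
               exo_torque = rep(0, n),
               u = matrix(0, 2, n, dimnames = list(c("ankle_r", "subtalar_r"), NULL)))
  exo <- base
  exo$com_vel <- sweep(base$com_vel, 2, dv, "+")
  if (!is.null(exo_torque)) exo$exo_torque <- exo_torque
  if (!is.null(u_ankle)) exo$u["ankle_r", ] <- u_ankle
  list(exo = exo, baseline = base, window = w,
       condition = list(device = device, peak_time = peak_time,
                        mode = "muscle_driven", peak_torque = peak_torque))
}

fake_normalizers <- function() {
  list(h_com = 1.03, g = 9.81, mass = 72.4, foot_width = 0.11,
       froude_v = sqrt(9.81 * 1.03), wbam = 72.4 * 1.03 * sqrt(9.81 * 1.03))
}

test_that("delta outcomes: identity, construction, Froude arithmetic", {
  nz <- fake_normalizers()
  r0 <- delta_outcomes(fake_pair(), nz)
  expect_equal(r0$d_vel_x, 0); expect_equal(r0$d_acc_y, 0)
  expect_equal(r0$label_vel_x, "none")

  r1 <- delta_outcomes(fake_pair(dv = c(0.01, 0, 0)), nz)
  expect_equal(r1$d_vel_x, 0.01, tolerance = 1e-12)
  expect_equal(r1$label_vel_x, "forward")

  # Froude normalization: 0.0318 m/s over sqrt(9.81 * 1.03) = 0.0100
  r2 <- delta_outcomes(fake_pair(dv = c(0.0318, 0, 0)), nz)
  expect_equal(r2$d_vel_x_n, 0.0318 / sqrt(9.81 * 1.03), tolerance = 1e-12)
  expect_equal(round(r2$d_vel_x_n, 4), 0.0100)

  # normalization round trip at 1e-12
  expect_equal(r2$d_vel_x_n * nz$froude_v, r2$d_vel_x, tolerance = 1e-12)
  expect_equal(r2$d_pos_y_n * nz$h_com, r2$d_pos_y, tolerance = 1e-12)

  # direction labels
  r3 <- delta_outcomes(fake_pair(dv = c(-0.01, -0.02, 0.03)), nz)
  expect_equal(r3$label_vel_x, "backward")
  expect_equal(r3$label_vel_y, "down")
  expect_equal(r3$label_vel_z, "lateral")
})

test_that("mismatched grids are rejected", {
  nz <- fake_normalizers()
  p <- fake_pair()
  p$exo$time <- p$exo$time + 0.01
  expect_error(delta_outcomes(p, nz), "mismatched")
})

test_that("exoskeleton power statistics", {
  # constant torque tau and speed w > 0: mean positive = tau*w/mass
  n <- length(seq(0.33, 0.495, by = 1e-3))
  p1 <- fake_pair(exo_torque = rep(7.24, n), u_ankle = rep(-2, n))
  # PF device sign is -1: power = sign * torque * u = (-1)*7.24*(-2) > 0
  pw <- exo_power_stats(p1)
  expect_equal(pw$mean_positive, 7.24 * 2 / 72.4, tolerance = 1e-9)
  expect_equal(pw$mean_negative, 0)

  # zero speed: both zero
  pw0 <- exo_power_stats(fake_pair(exo_torque = rep(7.24, n),
                                   u_ankle = rep(0, n)))
  expect_equal(pw0$mean_positive, 0); expect_equal(pw0$mean_negative, 0)

  # sinusoidal speed symmetric about zero with constant torque
  us <- sin(seq(0, 4 * pi, length.out = n))
  pws <- exo_power_stats(fake_pair(exo_torque = rep(7.24, n), u_ankle = us))
  expect_equal(pws$mean_positive, -pws$mean_negative, tolerance = 1e-3)
})

test_that("summaries: single record, ratio column, opposite signs", {
  nz <- fake_normalizers()
  r <- delta_outcomes(fake_pair(dv = c(0.03, 0, 0)), nz)
  s1 <- summarize_outcomes(r, walking_speed = 1.25)
  expect_equal(s1$by_group$d_vel_x_mean, 0.03, tolerance = 1e-12)
  expect_equal(s1$by_group$d_vel_x_sd, NA_real_)

  # the reported maximum velocity change over speed: 0.072/1.25 -> 6%
  r6 <- delta_outcomes(fake_pair(dv = c(0.072, 0, 0)), nz)
  s6 <- summarize_outcomes(r6, walking_speed = 1.25)
  expect_equal(round(s6$maxima$vel_ratio_pct[s6$maxima$class == "vel"]), 6)

  # two records of opposite sign, equal magnitude: mean zero
  ra <- delta_outcomes(fake_pair(dv = c(0.02, 0, 0)), nz)
  rb <- delta_outcomes(fake_pair(dv = c(-0.02, 0, 0)), nz)
  s2 <- summarize_outcomes(rbind(ra, rb), grouping = "device")
  expect_equal(s2$by_group$d_vel_x_mean, 0, tolerance = 1e-12)

  expect_error(summarize_outcomes(NULL), "no outcome")
})

test_that("linearity scan input validation and slope scaling", {
  m <- fix_model(); ref <- fix_reference()
  expect_error(linearity_scan(m, ref, magnitudes = c(0, 0, 0)), "degenerate")
  expect_error(linearity_scan(m, ref, magnitudes = c(0.1, 0.2, 0.3)))
  expect_error(linearity_scan(m, ref, magnitudes = c(0.05, 0.1)))
})
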