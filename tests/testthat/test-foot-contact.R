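# Smoothed Hunt-Crossley contact, per-foot GRF/COP, gait events.

test_that("sphere force: smoothing tail, Hertz term, friction asymptote", {
  r <- 0.025
  # 5 mm above ground: at most 1 N
  f_above <- sphere_ground_force(c(0, r + 0.005, 0), radius = r)
  expect_lt(abs(f_above$fn), 1)

  # static penetration: k delta^(3/2) within 1%
  delta <- 0.005
  f_pen <- sphere_ground_force(c(0, r - delta, 0), radius = r)
  expect_lt(abs(f_pen$fn - 1e6 * delta^1.5) / (1e6 * delta^1.5), 0.01)
  expect_equal(f_pen$point, c(0, -delta, 0), tolerance = 1e-12)

  # sliding fast: |tangential| / N -> mu_dynamic within 2% (no viscous term)
  p <- default_contact_params(); p$mu_viscous <- 0
  f_sl <- sphere_ground_force(c(0, r - delta, 0), velocity = c(2, 0, 0),
                              params = p)
  ft <- sqrt(f_sl$force[1]^2 + f_sl$force[3]^2)
  expect_lt(abs(ft / f_sl$force[2] - p$mu_dynamic) / p$mu_dynamic, 0.02)
  expect_lt(f_sl$force[1], 0)  # opposes slip

  # monotone nondecreasing in penetration at fixed velocity
  dep <- seq(-0.005, 0.01, length.out = 100)
  fn <- vapply(dep, function(d)
    sphere_ground_force(c(0, r - d, 0), radius = r)$fn, 0)
  expect_true(all(diff(fn) >= 0))

  # dissipation power >= 0 while penetrating
  set.seed(5)
  for (i in 1:50) {
    d <- runif(1, 0.001, 0.01); vy <- -runif(1, 0, 1)
    fh <- sphere_ground_force(c(0, r - d, 0), velocity = c(0, vy, 0))
    f0 <- sphere_ground_force(c(0, r - d, 0))
    expect_gte(fh$fn, f0$fn)  # extra force from dissipation resists approach
  }
})

test_that("per-foot GRF and COP", {
  m <- fix_model()
  ref <- fix_reference()
  # mid-stance state: COP defined for right foot, inside the contact hull
  i <- which.min(abs(ref$time - 0.3 * ref$T))
  st <- kinematic_state(m, ref$q[, i], ref$u[, i])
  g <- foot_grf(m, st)
  expect_true(g$right$cop_defined)
  pts <- g$sphere_point[which(m$sphere_foot == 0), ]
  fy <- g$sphere_force[which(m$sphere_foot == 0), 2]
  on <- fy > 1e-3
  expect_gte(g$right$cop[1], min(pts[on, 1]) - 1e-3)
  expect_lte(g$right$cop[1], max(pts[on, 1]) + 1e-3)
  expect_gte(g$right$cop[3], min(pts[on, 3]) - 1e-3)
  expect_lte(g$right$cop[3], max(pts[on, 3]) + 1e-3)
  # COP is the vertical-force weighted contact point
  expect_equal(g$right$cop[1], sum(fy * pts[, 1]) / sum(fy), tolerance = 1e-9)

  # airborne foot: flagged undefined
  q_air <- ref$q[, i]; q_air[2] <- q_air[2] + 1
  g2 <- foot_grf(m, kinematic_state(m, q_air))
  expect_false(g2$right$cop_defined)
  expect_true(is.na(g2$right$cop[1]))

  # standing flat on both feet with the pelvis height solved for body
  # weight: total vertical GRF within 0.5% of weight
  q0 <- numeric(23)
  w_target <- 72.4 * 9.81
  fy_tot <- function(ty) {
    q0[2] <- ty
    gg <- foot_grf(m, kinematic_state(m, q0))
    gg$right$force[2] + gg$left$force[2] - w_target
  }
  ty_star <- uniroot(fy_tot, c(1.0, 1.25), tol = 1e-12)$root
  q0[2] <- ty_star
  gg <- foot_grf(m, kinematic_state(m, q0))
  expect_lt(abs(gg$right$force[2] + gg$left$force[2] - w_target) / w_target,
            0.005)
})

test_that("gait event detection on constructed force profiles", {
  tt <- seq(0, 1.1, by = 0.001)
  pct <- tt / 1.1 * 100
  trap <- function(lo, hi, amp = 400) {
    amp * pmin(pmax((pct - lo) / 2, 0), 1) * pmin(pmax((hi - pct) / 2, 0), 1)
  }
  # heel group loaded 0-45 %GC, forefoot 10-63 %GC
  sph <- cbind(heel = trap(0, 45), mid = trap(2, 45),
               met = trap(10, 63), toe = trap(15, 63))
  ev <- detect_gait_events(tt, sph, c("heel", "mid", "met", "toe"))
  expect_lt(abs(ev$foot_flat - 10), 0.3)
  expect_lt(abs(ev$heel_off - 45), 0.3)
  expect_lt(abs(ev$toe_off - 63), 0.3)

  # constant zero force: error
  expect_error(detect_gait_events(tt, sph * 0, c("heel", "mid", "met", "toe")),
               "no stance")

  # step width from lateral COP offsets +-0.085 m
  ev2 <- detect_gait_events(tt, sph, c("heel", "mid", "met", "toe"),
                            cop_z_left = rep(-0.085, length(tt)),
                            cop_z_right = rep(0.085, length(tt)))
  expect_equal(ev2$step_width, 0.17, tolerance = 1e-12)
})
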