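# Synthetic periodic reference gait at 1.25 m/s. Stands in for the
# motion-capture + tracking input of the original two-step pipeline:
# pelvis and foot trajectories are designed directly (with contact loads
# built in), leg joint angles follow from inverse kinematics, and every
# coordinate is represented by a truncated Fourier series, so trajectories
# are periodic by construction with analytic derivatives.

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

#' Synthetic gait generator parameters
#'
#' Defaults describe walking at 1.25 m s^-1 with a 1.1 s cycle (0% = right
#' heel strike): designed toe-off at 63.5 %GC, foot-flat near 12.5 %GC,
#' heel-off near 42 %GC, foot centerlines +-0.085 m from the midline
#' (0.17 m step width), subtalar everted about 3 degrees in stance and
#' inverted near toe-off, pelvis vertical oscillation sized so the designed
#' vertical load varies between about 0.7 and 1.3 body weight.
#'
#' @param speed walking speed, m/s.
#' @param cycle_duration gait cycle duration, s.
#' @param n_harmonics Fourier harmonics kept per coordinate.
#' @param n_nodes inverse-kinematics nodes per cycle.
#' @param seed integer seed (used only by [add_observation_noise()] and
#'   carried for reproducibility bookkeeping).
#' @export
gait_params <- function(speed = 1.25, cycle_duration = 1.1,
                        n_harmonics = 30, n_nodes = 264, seed = 1L) {
  stopifnot(speed > 0, cycle_duration > 0)
  stride <- speed * cycle_duration
  list(
    speed = speed, T = cycle_duration, stride = stride,
    n_harmonics = n_harmonics, n_nodes = n_nodes, seed = as.integer(seed),
    s_toe_off = 0.635,          # designed end of stance (fraction of cycle)
    s_heel_off = 0.38,          # heel rise begins
    foot_z = 0.110,             # foot centerline lateral offset, m
    x0 = 0.0,                   # right heel-strike anchor, m
    tx0 = -0.31,                # pelvis fore-aft position at s = 0
    ty0 = 1.045, tyA = 0.017,   # pelvis height mean / oscillation
    tzA = 0.018,                # pelvis lateral sway amplitude
    hs_pitch = 0.18,            # toes-up foot pitch at heel strike, rad
    lift_pitch = 0.50,          # heel-up pitch at toe-off, rad
    st_stance = -0.052,         # subtalar angle in stance (everted), rad
    st_toeoff = 0.012,          # subtalar angle near toe-off (inverted)
    swing_clear = 0.045,        # extra forefoot clearance in swing, m
    load_floor = 1.0)           # N, keeps the stance pose solve bounded
}

# pelvis trajectory and its derivatives at cycle fractions s
pelvis_curves <- function(par, s) {
  w2 <- 4 * pi; w1 <- 2 * pi
  ty <- par$ty0 + par$tyA * cos(w2 * (s - 0.30))
  dty <- -par$tyA * w2 * sin(w2 * (s - 0.30))
  d2ty <- -par$tyA * w2^2 * cos(w2 * (s - 0.30))
  tz <- par$tzA * sin(w1 * (s - 0.05))
  list(tx = par$tx0 + par$stride * s, ty = ty, tz = tz,
       dty_ds = dty, d2ty_ds2 = d2ty)
}

# designed per-foot vertical load (N) for the right foot at cycle fraction s
foot_load <- function(par, s, mass, gravity = 9.81) {
  s <- s %% 1
  pc <- pelvis_curves(par, s)
  ftot <- mass * (gravity + pc$d2ty_ds2 / par$T^2)
  w <- smoothstep(s / 0.13) * (1 - smoothstep((s - 0.515) / 0.135))
  pmax(w * ftot, 0)
}

# designed right-foot pitch (rad, + toes up), subtalar and MTP angles
foot_angles <- function(par, s) {
  s <- s %% 1
  sto <- par$s_toe_off
  pitch <- par$hs_pitch * (1 - smoothstep((s - 0.045) / 0.115)) -
    par$lift_pitch * smoothstep((s - par$s_heel_off) / (sto + 0.015 - par$s_heel_off)) *
      (1 - smoothstep((s - 0.70) / 0.25))
  # swing: recover toward heel-strike pitch
  pitch <- pitch + par$hs_pitch * smoothstep((s - 0.82) / 0.17) * (s > sto)
  st <- par$st_stance +
    (par$st_toeoff - par$st_stance) * smoothstep((s - 0.46) / (sto - 0.42)) *
      (1 - smoothstep((s - 0.70) / 0.26)) +
    # settle from neutral back to stance eversion across heel strike
    (0 - par$st_stance) * smoothstep((s - 0.72) / 0.18) *
      (1 - smoothstep((s - 0.92) / 0.08))
  mtp <- 0.1 * softplus_r(-pitch / 0.1)
  list(pitch = pitch, st = st, mtp = mtp)
}

softplus_r <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# sphere bottom heights for a candidate calcaneus pose (right foot template;
# geometry mirrored for the left via the model itself). Returns total and
# group vertical Hertz forces for the designed-load solve.
.calcn_sphere_geom <- function(spec) {
  hs <- spec$height / 1.80
  right <- Filter(function(sp) sp$foot == "r", spec$spheres)
  list(loc = vapply(right, function(sp) sp$loc, numeric(3)),
       radius = vapply(right, function(sp) sp$radius, 0),
       group = vapply(right, function(sp) sp$group, ""),
       on_toes = vapply(right, function(sp) grepl("toes", sp$body), TRUE),
       mtp_off = spec$segments$mtp_off)
}

.rotz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
.rotaxis <- function(ax, a) {
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# sphere positions relative to the calcaneus origin for the designed angles
.sphere_rel <- function(ang, geom) {
  st_ax <- c(0.684, 0.669, -0.290); st_ax <- st_ax / sqrt(sum(st_ax^2))
  R <- .rotz(ang$pitch) %*% .rotaxis(st_ax, ang$st)
  P <- matrix(0, 3, length(geom$radius))
  for (i in seq_along(geom$radius)) {
    loc <- geom$loc[, i]
    if (geom$on_toes[i]) {
      Rm <- R %*% .rotz(ang$mtp)
      P[, i] <- R %*% geom$mtp_off + Rm %*% loc
    } else P[, i] <- R %*% loc
  }
  list(R = R, P = P)
}

# vertical contact force of the right foot for calcn origin height cy and
# the designed angles; used to solve cy for the designed load
.foot_force_at <- function(cy, ang, geom, contact) {
  sr <- .sphere_rel(ang, geom)
  delta <- geom$radius - (cy + sr$P[2, ])
  sp <- softplus_r(delta * contact$smoothing) / contact$smoothing
  sum(contact$stiffness * sp^1.5)
}

solve_stance_height <- function(load, ang, geom, contact) {
  f <- function(cy) .foot_force_at(cy, ang, geom, contact) - load
  lo <- 0.02; hi <- 0.30
  if (f(lo) < 0) return(lo)
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# full right-foot calcaneus pose target at cycle fraction s (sf may exceed
# [0,1): x advances one stride per cycle)
foot_pose <- function(par, sf, mass, geom, contact) {
  k <- floor(sf); s <- sf - k
  ang <- foot_angles(par, s)
  sto <- par$s_toe_off
  in_stance <- s < sto + 0.02
  load <- foot_load(par, s, mass) + par$load_floor
  if (in_stance) {
    cy <- solve_stance_height(load, ang, geom, contact)
  } else {
    # swing: hold the lowest sphere a designed clearance above the ground
    sr <- .sphere_rel(ang, geom)
    minrel <- min(sr$P[2, ] - geom$radius)
    w <- pmin(pmax((s - sto) / (1 - sto), 0), 1)
    gap <- par$swing_clear * smoothstep(w / 0.3) * (1 - smoothstep((w - 0.55) / 0.45))
    cy_clear <- gap - minrel
    cy_st <- solve_stance_height(load, ang, geom, contact)
    bl <- smoothstep((s - sto) / 0.03) * (1 - smoothstep((s - 0.96) / 0.04))
    cy <- (1 - bl) * cy_st + bl * cy_clear
  }
  # fore-aft anchor: heel contact point early, metatarsal heads late
  st_ax <- c(0.684, 0.669, -0.290); st_ax <- st_ax / sqrt(sum(st_ax^2))
  R <- .rotz(ang$pitch) %*% .rotaxis(st_ax, ang$st)
  heel_x <- (R %*% geom$loc[, geom$group == "heel"])[1]
  met_x <- (R %*% geom$loc[, geom$group == "met"][, 1, drop = FALSE])[1]
  met_rest <- geom$loc[1, geom$group == "met"][1]
  heel_rest <- geom$loc[1, geom$group == "heel"]
  cx_heel <- par$x0 - heel_x
  cx_met <- par$x0 + (met_rest - heel_rest) - met_x
  wb <- smoothstep((s - (par$s_heel_off - 0.02)) / 0.06)
  cx <- (1 - wb) * cx_heel + wb * cx_met
  if (s > sto) {
    # swing advance to the next stride's heel anchor
    ang1 <- foot_angles(par, 0.9999)
    R1 <- .rotz(ang1$pitch) %*% .rotaxis(st_ax, ang1$st)
    cx_next <- par$x0 + par$stride - (R1 %*% geom$loc[, geom$group == "heel"])[1]
    s_sw0 <- sto
    w <- smoothstep((s - s_sw0) / (1 - s_sw0))
    cx_to <- cx_met
    cx <- (1 - w) * cx_to + w * cx_next
  }
  list(pos = c(cx + k * par$stride, cy, 0), R = R, ang = ang)
}

rotvec_from_matrix <- function(R) {
  ang <- acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1))
  if (ang < 1e-9) return(c(0, 0, 0))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(ang))
  ax * ang
}

# 6-DOF leg inverse kinematics: hip (3), knee, ankle, subtalar matching the
# calcaneus target pose; Newton with finite-difference Jacobian
ik_leg <- function(model, q, side, target_pos, target_R, theta0 = NULL) {
  coords <- paste0(c("hip_flexion_", "hip_adduction_", "hip_rotation_",
                     "knee_", "ankle_", "subtalar_"), side)
  idx <- coord_index(model, coords)
  calcn <- body_index(model, paste0("calcn_", side))
  u0 <- numeric(model$ndof)
  resid <- function(th) {
    q[idx] <- th
    K <- cpp_fk(model$ptr, q, u0)
    c(K$p[, calcn] - target_pos,
      rotvec_from_matrix(K$R[, , calcn] %*% t(target_R)))
  }
  newton <- function(th) {
    for (it in 1:40) {
      r <- resid(th)
      if (sqrt(sum(r^2)) < 1e-9) break
      J <- matrix(0, 6, 6)
      h <- 1e-6
      for (j in 1:6) {
        tp <- th; tp[j] <- tp[j] + h
        J[, j] <- (resid(tp) - r) / h
      }
      step <- tryCatch(solve(J, r), error = function(e) {
        solve(J + diag(1e-6, 6), r)
      })
      ns <- sqrt(sum(step^2))
      if (ns > 0.4) step <- step * 0.4 / ns
      th <- th - step
      # stay on the physiologic knee branch (no hyperextension)
      th[4] <- max(th[4], 0.02)
    }
    th
  }
  th <- newton(if (is.null(theta0)) c(0.4, 0, 0, 0.3, 0, -0.05) else theta0)
  r2 <- sqrt(sum(resid(th)^2))
  if (r2 > 1e-8) {
    th_alt <- newton(c(0.3, 0, 0, 0.6, -0.2, -0.05))
    if (sqrt(sum(resid(th_alt)^2)) < r2) {
      th <- th_alt; r2 <- sqrt(sum(resid(th)^2))
    }
  }
  list(theta = th, resid = r2)
}

#' Synthesize periodic joint trajectories
#'
#' Constructs one periodic gait cycle of coordinate trajectories: pelvis
#' curves are analytic, foot (calcaneus) poses are designed with the
#' foot-ground contact loads built in, leg joint angles follow from
#' inverse kinematics at \code{n_nodes} uniformly spaced nodes, and each
#' coordinate is then fit with a truncated Fourier series (periodic by
#' construction; speeds are analytic derivatives). The pelvis fore-aft
#' coordinate advances speed x time on top of its periodic part.
#'
#' @param params see [gait_params()].
#' @param model an \code{exo_model} (packaged default when omitted).
#' @return object of class \code{exo_gait_fit} with \code{eval(t)} giving
#'   \code{q}, \code{u}, \code{udot} matrices.
#' @export
synth_joint_trajectories <- function(params = gait_params(),
                                     model = build_reduced_model()) {
  par <- params
  spec <- model$spec
  geom <- .calcn_sphere_geom(spec)
  contact <- spec$contact
  mass <- model$total_mass
  N <- par$n_nodes
  s <- (0:(N - 1)) / N
  nq <- model$ndof
  Q <- matrix(0, nq, N)
  rownames(Q) <- model$coord_names

  pc <- pelvis_curves(par, s)
  Q["pelvis_tx", ] <- pc$tx
  Q["pelvis_ty", ] <- pc$ty
  Q["pelvis_tz", ] <- pc$tz

  mirror <- diag(c(1, 1, -1))
  th_r <- NULL; th_l <- NULL
  fail <- 0
  for (kk in seq_len(N)) {
    qk <- Q[, kk]
    # right leg
    fp <- foot_pose(par, s[kk], mass, geom, contact)
    sol <- ik_leg(model, qk, "r", fp$pos + c(0, 0, par$foot_z), fp$R, th_r)
    th_r <- sol$theta
    if (sol$resid > 1e-6) fail <- fail + 1
    Q[coord_index(model, paste0(c("hip_flexion_", "hip_adduction_",
                                  "hip_rotation_", "knee_", "ankle_",
                                  "subtalar_"), "r")), kk] <- th_r
    Q["mtp_r", kk] <- fp$ang$mtp
    # left leg: right curve advanced half a cycle, mirrored in z
    fpl <- foot_pose(par, s[kk] + 0.5, mass, geom, contact)
    pos_l <- c(fpl$pos[1] - par$stride / 2, fpl$pos[2], -par$foot_z)
    R_l <- mirror %*% fpl$R %*% mirror
    qk <- Q[, kk]
    sol_l <- ik_leg(model, qk, "l", pos_l, R_l, th_l)
    th_l <- sol_l$theta
    if (sol_l$resid > 1e-6) fail <- fail + 1
    Q[coord_index(model, paste0(c("hip_flexion_", "hip_adduction_",
                                  "hip_rotation_", "knee_", "ankle_",
                                  "subtalar_"), "l")), kk] <- th_l
    Q["mtp_l", kk] <- fpl$ang$mtp
  }
  if (fail > 0)
    warning(fail, " of ", 2 * N, " IK solves did not reach tolerance")

  # Fourier fit (periodic); pelvis_tx carries the linear advance
  lin <- numeric(nq)
  lin[coord_index(model, "pelvis_tx")] <- par$speed
  Qp <- Q
  Qp[coord_index(model, "pelvis_tx"), ] <- Q[coord_index(model, "pelvis_tx"), ] -
    par$speed * par$T * s
  H <- par$n_harmonics
  co <- apply(Qp, 1, function(y) {
    f <- stats::fft(y) / N
    a0 <- Re(f[1])
    a <- 2 * Re(f[2:(H + 1)])
    b <- -2 * Im(f[2:(H + 1)])
    c(a0, a, b)
  })
  fit <- list(params = par, a0 = co[1, ], A = co[2:(H + 1), , drop = FALSE],
              B = co[(H + 2):(2 * H + 1), , drop = FALSE], lin = lin,
              H = H, T = par$T, nq = nq, coord_names = model$coord_names,
              nodes = list(s = s, Q = Q), ik_failures = fail)
  class(fit) <- "exo_gait_fit"
  fit
}

#' Evaluate a fitted gait trajectory
#'
#' @param fit an \code{exo_gait_fit}.
#' @param t times, s (any range; trajectories are periodic).
#' @return list of matrices \code{q}, \code{u}, \code{udot} (DOF x length(t)).
#' @export
eval_gait <- function(fit, t) {
  Tc <- fit$T
  H <- fit$H
  nt <- length(t)
  w <- 2 * pi / Tc
  Q <- matrix(rep(fit$a0, nt), fit$nq, nt)
  U <- matrix(0, fit$nq, nt)
  UD <- matrix(0, fit$nq, nt)
  for (h in seq_len(H)) {
    ch <- cos(h * w * t); sh <- sin(h * w * t)
    Q <- Q + outer(fit$A[h, ], ch) + outer(fit$B[h, ], sh)
    U <- U + outer(fit$A[h, ], -h * w * sh) + outer(fit$B[h, ], h * w * ch)
    UD <- UD - (h * w)^2 * (outer(fit$A[h, ], ch) + outer(fit$B[h, ], sh))
  }
  Q <- Q + outer(fit$lin, t)
  U <- U + matrix(rep(fit$lin, nt), fit$nq, nt)
  rownames(Q) <- rownames(U) <- rownames(UD) <- fit$coord_names
  list(q = Q, u = U, udot = UD)
}
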