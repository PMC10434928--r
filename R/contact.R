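# Foot-ground contact: smoothed Hunt-Crossley sphere-plane forces, per-foot
# ground reaction force and center of pressure, and gait-event detection.

#' Smoothed Hunt-Crossley sphere-ground force
#'
#' Normal force k * delta^(3/2) * (1 + 1.5 c v_pen), with the penetration
#' passed through a softplus so the force is smooth (C1) across touchdown
#' and carries a tiny (<= 1 N) tail just above contact; tangential friction
#' opposes slip with a tanh-regularized Coulomb term plus a viscous term.
#' The force acts at the sphere-plane nearest point; the ground is y = 0.
#'
#' @param center,velocity sphere center position and velocity (3-vectors, m,
#'   m/s, world frame).
#' @param omega angular velocity of the carrying body (rad/s), used for the
#'   slip velocity of the contact point.
#' @param radius sphere radius, m.
#' @param params contact parameter list, see [default_contact_params()].
#' @return list: \code{force} (N, 3-vector), \code{point} (m), \code{fn}
#'   normal force magnitude (N).
#' @export
sphere_ground_force <- function(center, velocity = c(0, 0, 0),
                                omega = c(0, 0, 0), radius = 0.025,
                                params = default_contact_params()) {
  stopifnot(radius > 0, params$stiffness > 0, params$dissipation >= 0,
            params$mu_dynamic <= params$mu_static)
  out <- cpp_sphere_force(center, velocity, omega, radius, params)
  list(force = as.numeric(out$force), point = as.numeric(out$point),
       fn = out$fn)
}

#' Per-foot ground reaction force and center of pressure
#'
#' Sums the contact-sphere forces per foot and locates the center of
#' pressure: the point on the ground plane where the horizontal moment of
#' the vertical force distribution vanishes. The COP is flagged undefined
#' when the vertical force is below 10 N.
#'
#' @inheritParams forward_dynamics
#' @return list with per-foot entries \code{right}, \code{left}: total force
#'   (N), total moment about the world origin (N m), \code{cop} (m; NA when
#'   undefined), \code{cop_defined}; plus per-sphere forces and points.
#' @export
foot_grf <- function(model, state) {
  C <- cpp_contact_forces(model$ptr, state$q, state$u)
  mk <- function(i) list(force = as.numeric(C$foot_force[i, ]),
                         moment = as.numeric(C$foot_moment[i, ]),
                         cop = as.numeric(C$cop[i, ]),
                         cop_defined = C$cop_defined[i])
  list(right = mk(1), left = mk(2),
       sphere_force = C$sphere_force, sphere_point = C$sphere_point)
}

#' Detect gait events from contact force trajectories
#'
#' Works on one full gait cycle of per-sphere vertical force trajectories
#' for one foot. Events (as % gait cycle): foot-flat = first instant both
#' the heel and forefoot sphere groups exceed the force threshold; heel-off
#' = last instant the heel group exceeds the threshold before toe-off;
#' toe-off = the instant the foot's total vertical force drops below the
#' threshold (end of stance). Step width is the medio-lateral distance
#' between left- and right-foot COP at the respective mid-stance instants.
#'
#' @param time time grid over one cycle, s.
#' @param sphere_fy matrix (time x spheres) of vertical sphere forces for
#'   the foot of interest.
#' @param groups character vector per sphere: "heel", "mid", "met", "toe".
#' @param total_fy vertical GRF trajectory of the foot (defaults to the row
#'   sums of \code{sphere_fy}).
#' @param cop_z_left,cop_z_right optional lateral COP trajectories used for
#'   step width (otherwise NA returned for step width).
#' @param threshold force threshold, N (10 N default, a common gait-lab
#'   convention).
#' @return list: \code{foot_flat}, \code{heel_off}, \code{toe_off} in % gait
#'   cycle, \code{step_width} in m.
#' @export
detect_gait_events <- function(time, sphere_fy, groups,
                               total_fy = rowSums(sphere_fy),
                               cop_z_left = NULL, cop_z_right = NULL,
                               threshold = 10) {
  stopifnot(nrow(sphere_fy) == length(time), ncol(sphere_fy) == length(groups))
  pct <- (time - time[1]) / (time[length(time)] - time[1]) * 100
  heel <- rowSums(sphere_fy[, groups %in% c("heel", "mid"), drop = FALSE])
  fore <- rowSums(sphere_fy[, groups %in% c("met", "toe"), drop = FALSE])

  stance <- total_fy > threshold
  if (!any(stance)) stop("no stance phase detected (GRF never exceeds threshold)")

  # toe-off: end of the stance episode that starts at cycle begin
  to_idx <- which(!stance & pct > 5)
  toe_off <- if (length(to_idx)) pct[to_idx[1]] else 100

  ff_idx <- which(heel > threshold & fore > threshold & pct < toe_off)
  foot_flat <- if (length(ff_idx)) pct[ff_idx[1]] else NA_real_

  ho_idx <- which(heel > threshold & pct < toe_off)
  heel_off <- if (length(ho_idx)) pct[ho_idx[length(ho_idx)]] else NA_real_

  step_width <- NA_real_
  if (!is.null(cop_z_left) && !is.null(cop_z_right)) {
    # mid-stance of the right foot is ~ toe_off/2; left foot offset by 50%
    ms_r <- which.min(abs(pct - toe_off / 2))
    ms_l <- which.min(abs(pct - (toe_off / 2 + 50) %% 100))
    step_width <- abs(cop_z_right[ms_r] - cop_z_left[ms_l])
  }
  list(foot_flat = foot_flat, heel_off = heel_off, toe_off = toe_off,
       step_width = step_width)
}
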