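# Rigid-body operations: states, forward dynamics, passive forces, COM
# kinematics, whole-body angular momentum and small kinematic queries.

#' Create a kinematic state
#'
#' Bundles time, coordinate values \code{q} and coordinate speeds \code{u}.
#' Coordinates outside their model range are reported through the
#' \code{range_violations} attribute (coordinate names), never clamped.
#'
#' @param model an \code{exo_model}.
#' @param q,u numeric vectors of length \code{model$ndof}.
#' @param time time stamp in seconds.
#' @export
kinematic_state <- function(model, q, u = NULL, time = 0) {
  if (is.null(u)) u <- numeric(model$ndof)
  if (length(q) != model$ndof || length(u) != model$ndof)
    stop("q and u must have length ", model$ndof)
  viol <- which(q < model$flat$qmin | q > model$flat$qmax)
  st <- list(time = time, q = as.numeric(q), u = as.numeric(u))
  class(st) <- "exo_state"
  attr(st, "range_violations") <- model$coord_names[viol]
  st
}

#' Forward dynamics
#'
#' Solves \eqn{M(q)\,\dot u = \tau_{applied} + \tau_{gravity} +
#' \tau_{coriolis}} for the coordinate accelerations. Contact, muscle and
#' passive forces are not added implicitly; fold them into \code{applied}.
#'
#' @param model an \code{exo_model}.
#' @param state an \code{exo_state}.
#' @param applied generalized force vector (length = DOF count).
#' @return coordinate accelerations (rad s^-2 or m s^-2).
#' @export
forward_dynamics <- function(model, state, applied = numeric(model$ndof)) {
  if (length(applied) != model$ndof)
    stop("applied forces must have length ", model$ndof)
  as.numeric(cpp_forward_dynamics(model$ptr, state$q, state$u, applied))
}

#' Mass matrix at a configuration
#' @inheritParams forward_dynamics
#' @param q coordinate vector.
#' @export
mass_matrix <- function(model, q) {
  M <- cpp_mass_matrix(model$ptr, q)
  dimnames(M) <- list(model$coord_names, model$coord_names)
  M
}

#' Passive generalized forces
#'
#' Sum of the linear joint springs (lumbar, MTP, ankle-subtalar bushing),
#' coordinate dampers, and exponential range-of-motion guard springs, with
#' each component separately queryable.
#'
#' @inheritParams forward_dynamics
#' @return matrix (DOF x 4) with columns \code{spring}, \code{damper},
#'   \code{expo}, \code{total}, in N m (or N for sliders).
#' @export
passive_generalized_forces <- function(model, state) {
  P <- cpp_passive_forces(model$ptr, state$q, state$u)
  dimnames(P) <- list(model$coord_names, c("spring", "damper", "expo", "total"))
  P
}

#' Center-of-mass kinematics
#'
#' Mass-weighted COM position, velocity, and acceleration (from the body
#' accelerations implied by \code{udot}).
#'
#' @inheritParams forward_dynamics
#' @param udot coordinate accelerations, typically from [forward_dynamics()].
#' @return list with \code{pos}, \code{vel}, \code{acc} (3-vectors, m, m/s,
#'   m/s^2; x forward, y up, z right).
#' @export
com_kinematics <- function(model, state, udot = numeric(model$ndof)) {
  out <- cpp_com(model$ptr, state$q, state$u, udot)
  lapply(out, as.numeric)
}

#' Whole-body angular momentum about the COM
#'
#' \eqn{H = \sum_i (I_i \omega_i + m_i\, r_i \times v_i)} with positions and
#' velocities taken relative to the whole-body COM.
#'
#' @inheritParams forward_dynamics
#' @return 3-vector, kg m^2 s^-1.
#' @export
whole_body_angular_momentum <- function(model, state) {
  as.numeric(cpp_wbam(model$ptr, state$q, state$u))
}

#' Body poses and velocities (forward kinematics)
#'
#' @inheritParams forward_dynamics
#' @param bodies character vector of body names; default all.
#' @return named list per body: rotation matrix \code{R}, origin \code{p},
#'   angular velocity \code{w}, origin velocity \code{v} (world frame).
#' @export
body_kinematics <- function(model, state, bodies = NULL) {
  K <- cpp_fk(model$ptr, state$q, state$u)
  idx <- if (is.null(bodies)) seq_len(model$ndof) else body_index(model, bodies)
  out <- lapply(idx, function(i) list(R = K$R[, , i], p = K$p[, i],
                                      w = K$w[, i], v = K$v[, i]))
  names(out) <- model$body_names[idx]
  out
}

#' Kinetic and gravitational potential energy
#' @inheritParams forward_dynamics
#' @export
model_energy <- function(model, state) {
  cpp_energy(model$ptr, state$q, state$u)
}

#' Generalized forces equivalent to a wrench on one body
#'
#' Projects a torque/force applied to a body (force acting at \code{point},
#' world frame) into generalized coordinates via the Jacobian transpose.
#'
#' @inheritParams forward_dynamics
#' @param body body name.
#' @param torque,force,point 3-vectors (world frame).
#' @export
generalized_from_wrench <- function(model, state, body,
                                    torque = c(0, 0, 0), force = c(0, 0, 0),
                                    point = c(0, 0, 0)) {
  bi <- body_index(model, body) - 1L
  setNames(as.numeric(cpp_generalized_from_wrench(
    model$ptr, state$q, bi, torque, force, point)), model$coord_names)
}
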