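# Hill-type muscle mechanics: activation dynamics, characteristic curves,
# tendon-force state dynamics and joint-moment production. Activation and
# normalized tendon force are the muscle state variables; tendon compliance
# (strain 0.10 at maximum isometric force) is enabled only for the
# plantarflexors with long tendons (soleus, gastrocnemius heads).

#' First-order smooth activation dynamics
#'
#' Returns da/dt for excitation \code{e} and activation \code{a}. The rate
#' blends activation and deactivation time constants with a smooth tanh
#' switch, so it is continuous in both arguments, and is faster when
#' \code{e > a} (activation, tau = 0.015 s default) than when \code{e < a}
#' (deactivation, tau = 0.060 s default).
#'
#' @param excitation,activation values in \[0, 1\] (vectorized).
#' @param tau_act,tau_deact time constants, s.
#' @export
activation_dynamics <- function(excitation, activation,
                                tau_act = 0.015, tau_deact = 0.060) {
  stopifnot(all(excitation >= -1e-9 & excitation <= 1 + 1e-9),
            all(activation >= -1e-9 & activation <= 1 + 1e-9))
  n <- max(length(excitation), length(activation))
  as.numeric(cpp_act_rate(rep_len(excitation, n), rep_len(activation, n),
                          tau_act, tau_deact))
}

#' Muscle characteristic curves
#'
#' Active force-length (Gaussian sum, maximal and equal to 1 at normalized
#' fiber length 1), passive force-length (smooth exponential, approximately
#' zero below optimal length, nondecreasing), and force-velocity
#' (asinh-shaped; 1 at zero velocity, near zero at maximal shortening
#' velocity, a plateau above 1 when lengthening).
#'
#' @param lM_tilde normalized fiber length(s), > 0.
#' @param vM_tilde normalized fiber velocity(s) (fiber velocities divided by
#'   the maximum contraction velocity, 10 optimal fiber lengths per second).
#' @return data frame with columns \code{f_active_length},
#'   \code{f_passive_length}, \code{f_velocity}.
#' @export
characteristic_curves <- function(lM_tilde, vM_tilde = 0) {
  stopifnot(all(lM_tilde > 0))
  n <- max(length(lM_tilde), length(vM_tilde))
  lM_tilde <- rep_len(lM_tilde, n); vM_tilde <- rep_len(vM_tilde, n)
  data.frame(
    f_active_length = as.numeric(cpp_fal(lM_tilde)),
    f_passive_length = as.numeric(cpp_fpe(lM_tilde)),
    f_velocity = as.numeric(cpp_fv(vM_tilde)))
}

#' Normalized tendon force from normalized tendon length
#'
#' Quadratic-in-smoothed-strain tendon curve: approximately zero at or below
#' slack length (within 0.01), strictly increasing above slack, convex, and
#' exactly 1 at strain \code{eps0} (0.10 for the compliant plantarflexor
#' tendons) by construction.
#'
#' @param lT_tilde tendon length / slack length, > 0 (vectorized).
#' @param eps0 tendon strain at maximum isometric force.
#' @export
tendon_force_from_length <- function(lT_tilde, eps0 = 0.10) {
  stopifnot(all(lT_tilde > 0), eps0 > 0)
  as.numeric(cpp_tendon_force(lT_tilde, eps0))
}

#' Tendon-force state derivative
#'
#' For a compliant muscle, inverts the tendon curve to the current tendon
#' length, solves the fiber-tendon force equilibrium for the required
#' force-velocity value, inverts the force-velocity curve for the fiber
#' velocity (clamped to +-1 normalized and reported when outside range), and
#' returns the normalized tendon-force rate.
#'
#' @param params a single muscle parameter list with fields \code{fiso},
#'   \code{lopt}, \code{lts}, \code{alpha}, \code{eps0}, \code{vmax}; e.g.
#'   an element of [default_muscle_table()] with \code{eps0} set.
#' @param activation activation in \[0, 1\].
#' @param ft_tilde normalized tendon force state.
#' @param lMT,vMT muscle-tendon length (m) and lengthening velocity (m/s).
#' @return list: \code{dft} (1/s) and \code{clamped} (logical).
#' @export
tendon_force_state_derivative <- function(params, activation, ft_tilde,
                                          lMT, vMT) {
  if (is.null(params$eps0) || is.na(params$eps0) || params$eps0 <= 0)
    stop("tendon_force_state_derivative requires a compliant muscle (eps0 > 0)")
  stopifnot(activation >= 0, activation <= 1, ft_tilde >= 0)
  cpp_tendon_state_deriv(params$fiso, params$lopt, params$lts, params$alpha,
                         params$eps0, params$vmax %||% 10,
                         activation, ft_tilde, lMT, vMT)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Muscle-generated joint moments
#'
#' Tendon forces of all muscles at the given state, and the generalized
#' forces they produce: the force on coordinate j is the sum over muscles of
#' moment arm times tendon force, with the moment arm equal to minus the
#' muscle-tendon length derivative with respect to the coordinate.
#'
#' @inheritParams forward_dynamics
#' @param activations vector (one per muscle) in \[0, 1\].
#' @param ft_tilde normalized tendon forces of the compliant muscles, in
#'   model order (default: isometric equilibrium not assumed; zeros).
#' @return list: \code{FT} tendon forces (N, named), \code{tau} generalized
#'   forces (N m, named).
#' @export
muscle_generalized_forces <- function(model, state,
                                      activations = numeric(model$n_muscles),
                                      ft_tilde = numeric(model$n_ft)) {
  stopifnot(length(activations) == model$n_muscles,
            length(ft_tilde) == model$n_ft)
  out <- cpp_muscle_forces(model$ptr, state$q, state$u, activations, ft_tilde)
  list(FT = setNames(as.numeric(out$FT), model$muscle_names),
       tau = setNames(as.numeric(out$tau), model$coord_names))
}

#' Muscle-tendon lengths, velocities and moment arms
#'
#' @inheritParams forward_dynamics
#' @return list: \code{lmt} (m), \code{vmt} (m/s), \code{arms} (muscles x
#'   DOF matrix of moment arms, m).
#' @export
muscle_geometry <- function(model, state) {
  g <- cpp_muscle_geometry(model$ptr, state$q, state$u)
  rownames(g$arms) <- model$muscle_names
  colnames(g$arms) <- model$coord_names
  g$lmt <- setNames(as.numeric(g$lmt), model$muscle_names)
  g$vmt <- setNames(as.numeric(g$vmt), model$muscle_names)
  g
}

#' Export the characteristic curves as a data frame / CSV
#'
#' Dense scan of the normalized curves for visual validation.
#' @param path optional file path; when given, written as CSV.
#' @param n grid size.
#' @export
export_characteristic_curves <- function(path = NULL, n = 201) {
  l <- seq(0.4, 1.8, length.out = n)
  v <- seq(-1.2, 1.2, length.out = n)
  out <- cbind(data.frame(lM_tilde = l, vM_tilde = v),
               characteristic_curves(l, 0)[, 1:2],
               f_velocity = characteristic_curves(1, v)$f_velocity,
               f_tendon = tendon_force_from_length(seq(0.95, 1.12, length.out = n)),
               lT_tilde = seq(0.95, 1.12, length.out = n))
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  invisible(out)
}
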