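# Perturbation engine: forward-integrates 15 %GC windows with exoskeleton
# torques in muscle-driven or torque-driven mode, plus the matched
# zero-torque baseline from the identical initial state. All "changes" are
# exo minus baseline at matched times, which cancels any residual dynamic
# inconsistency of the reference.

#' Simulation window for a peak time
#'
#' Onset = peak - rise, end = peak + fall; with the default four-parameter
#' profile the window spans 15% of the gait cycle.
#'
#' @param peak_time %GC of peak torque.
#' @param cycle_duration cycle duration, s.
#' @param rise,fall rise and fall, %GC.
#' @export
sim_window <- function(peak_time, cycle_duration, rise = 10, fall = 5) {
  onset <- peak_time - rise; end <- peak_time + fall
  stopifnot(onset >= 0, end <= 100)
  list(onset_pct = onset, peak_pct = peak_time, end_pct = end,
       t_on = onset / 100 * cycle_duration,
       t_peak = peak_time / 100 * cycle_duration,
       t_end = end / 100 * cycle_duration)
}

#' Initial state at a window onset
#'
#' Interpolates the reference at the onset time: coordinates and speeds from
#' the analytic (Fourier) gait representation (exact), activations and
#' normalized tendon forces linearly from the stored tables.
#'
#' @param model an \code{exo_model}.
#' @param ref an \code{exo_reference}.
#' @param onset_pct onset, %GC in \[0, 100).
#' @param mode "muscle_driven" or "torque_driven".
#' @return full state vector in integrator layout.
#' @export
initial_state_at <- function(model, ref, onset_pct, mode = "muscle_driven") {
  stopifnot(onset_pct >= 0, onset_pct < 100)
  if (mode == "muscle_driven" && (is.null(ref$a) || is.null(ref$e)))
    stop("reference is missing muscle states")
  t0 <- onset_pct / 100 * ref$T
  tr <- eval_gait(ref$gait_fit, t0)
  y <- c(tr$q[, 1], tr$u[, 1])
  if (mode == "muscle_driven") {
    a0 <- vapply(seq_len(nrow(ref$a)), function(m)
      approx(ref$time, ref$a[m, ], xout = t0, rule = 2)$y, 0)
    y <- c(y, a0)
    if (model$n_ft > 0) {
      ft0 <- vapply(seq_len(nrow(ref$ft)), function(k)
        approx(ref$time, ref$ft[k, ], xout = t0, rule = 2)$y, 0)
      y <- c(y, ft0)
    }
  }
  y
}

#' Torque-driven model variant
#'
#' Replaces the muscles by prescribed per-coordinate moment trajectories:
#' the muscle-generated generalized forces recomputed along the reference.
#' Passive joint forces remain state-dependent; the prescribed moments do
#' not respond to the state.
#'
#' @param model an \code{exo_model}.
#' @param ref an \code{exo_reference} (must include muscle states).
#' @return control table list for the integrator (prescribed moments
#'   included), to be passed as \code{ctrl} to [integrate_window()].
#' @export
make_torque_driven <- function(model, ref) {
  if (is.null(ref$pm)) stop("reference lacks prescribed muscle moments")
  reference_controls(ref, torque_driven = TRUE)
}

#' Forward-integrate one simulation window
#'
#' Adaptive embedded 4th/5th-order Runge-Kutta (Dormand-Prince) with
#' absolute and relative tolerance equal to \code{accuracy}, dense output at
#' 1 kHz, and full trajectory bookkeeping (per-foot GRF/COP, COM kinematics
#' from the external-force resultant, whole-body angular momentum, applied
#' exoskeleton torque). Range-of-motion violations are logged with their
#' first time stamp, not fatal.
#'
#' @param model an \code{exo_model}.
#' @param y0 initial state (layout per mode).
#' @param t0,t1 window start/end, s.
#' @param ctrl control tables ([reference_controls()] or
#'   [make_torque_driven()]).
#' @param mode "muscle_driven" or "torque_driven".
#' @param exo exoskeleton actuation list (internal layout); use
#'   [run_condition()] for the high-level interface.
#' @param accuracy integrator tolerance (default 1e-6).
#' @param dense_dt dense-output step, s.
#' @return object of class \code{exo_trajectory}.
#' @export
integrate_window <- function(model, y0, t0, t1, ctrl, mode = "muscle_driven",
                             exo = NULL, accuracy = 1e-6, dense_dt = 1e-3) {
  imode <- match(mode, c("muscle_driven", "torque_driven")) - 1L
  if (is.na(imode)) stop("unknown mode: ", mode)
  if (is.null(exo))
    exo <- list(t_on = t0, t_peak = (t0 + t1) / 2, t_end = t1, peak = 0,
                joints = integer(0), signs = numeric(0))
  out <- cpp_integrate_window(model$ptr, y0, t0, t1, ctrl, imode, exo,
                              accuracy, accuracy, dense_dt, 2000000L)
  nq <- model$ndof
  traj <- list(
    time = as.numeric(out$time),
    q = out$Y[seq_len(nq), , drop = FALSE],
    u = out$Y[nq + seq_len(nq), , drop = FALSE],
    Y = out$Y, mode = mode,
    grf_r = out$grf_r, grf_l = out$grf_l,
    cop_r = out$cop_r, cop_l = out$cop_l,
    cop_r_defined = as.logical(out$cop_r_defined),
    cop_l_defined = as.logical(out$cop_l_defined),
    com_pos = out$com_pos, com_vel = out$com_vel, com_acc = out$com_acc,
    wbam = out$wbam, exo_torque = as.numeric(out$exo_torque),
    stats = list(nsteps = out$nsteps, nreject = out$nreject,
                 n_fv_clamp = out$n_fv_clamp, n_rom = out$n_rom,
                 rom_first_time = out$rom_first_time))
  rownames(traj$q) <- rownames(traj$u) <- model$coord_names
  class(traj) <- "exo_trajectory"
  traj
}

# exoskeleton actuation in the integrator layout
exo_actuation <- function(model, device, window, peak_torque, mass) {
  joints <- vapply(device$joints, function(j) coord_index(model, j$coord), 0L)
  signs <- vapply(device$joints, function(j) j$sign, 0)
  list(t_on = window$t_on, t_peak = window$t_peak, t_end = window$t_end,
       peak = peak_torque * mass, joints = joints - 1L, signs = signs)
}

#' Run one exoskeleton condition (exo + matched baseline)
#'
#' Simulates the 15 %GC window from the reference state at torque onset,
#' once with the device torque profile and once with zero torque, sharing
#' the initial state, controls and integrator settings. Results are cached
#' by condition key in \code{cache} (an environment) when supplied.
#'
#' @param model an \code{exo_model}.
#' @param ref an \code{exo_reference}.
#' @param device device id (see [exo_device_ids()]) or an \code{exo_device}.
#' @param peak_time peak torque time, %GC.
#' @param mode "muscle_driven" or "torque_driven".
#' @param peak_torque peak magnitude, N m kg^-1.
#' @param accuracy integrator tolerance.
#' @param cache optional environment for memoizing exo/baseline pairs.
#' @return list: \code{exo}, \code{baseline} (class \code{exo_trajectory}),
#'   \code{window}, \code{condition}.
#' @export
run_condition <- function(model, ref, device, peak_time,
                          mode = c("muscle_driven", "torque_driven"),
                          peak_torque = 0.1, accuracy = 1e-6, cache = NULL) {
  mode <- match.arg(mode)
  if (is.character(device)) device <- exo_device(device)
  window <- sim_window(peak_time, ref$T)
  key <- sprintf("%s_p%g_t%g_%s", device$id, peak_time, peak_torque, mode)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])

  ctrl <- if (mode == "muscle_driven") reference_controls(ref)
          else make_torque_driven(model, ref)
  y0 <- initial_state_at(model, ref, window$onset_pct, mode)
  exo <- exo_actuation(model, device, window, peak_torque, ref$mass)

  bkey <- sprintf("baseline_o%g_%s", window$onset_pct, mode)
  baseline <- if (!is.null(cache) && !is.null(cache[[bkey]])) {
    cache[[bkey]]
  } else {
    b <- integrate_window(model, y0, window$t_on, window$t_end, ctrl, mode,
                          exo = NULL, accuracy = accuracy)
    if (!is.null(cache)) cache[[bkey]] <- b
    b
  }
  exo_traj <- integrate_window(model, y0, window$t_on, window$t_end, ctrl,
                               mode, exo = exo, accuracy = accuracy)
  out <- list(exo = exo_traj, baseline = baseline, window = window,
              condition = list(device = device$id, peak_time = peak_time,
                               mode = mode, peak_torque = peak_torque,
                               key = key))
  if (!is.null(cache)) cache[[key]] <- out
  out
}
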