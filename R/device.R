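# Exoskeleton devices: the four-parameter torque profile, the five device
# definitions, and the device x peak-time x mode condition grid.

#' Four-parameter exoskeleton torque profile parameters
#'
#' Peak time in % gait cycle (grid: 20 to 60 by 5), rise time 10 %GC, fall
#' time 5 %GC, peak magnitude 0.1 N m per kg body mass. The nonzero support
#' (rise + fall = 15 %GC) equals the simulated window length.
#'
#' @param peak_time %GC of peak torque.
#' @param rise,fall rise and fall times, %GC.
#' @param peak_torque peak magnitude, N m kg^-1 (configurable for linearity
#'   scans).
#' @param mass subject mass, kg.
#' @export
torque_profile_params <- function(peak_time, rise = 10, fall = 5,
                                  peak_torque = 0.1, mass = 72.4) {
  stopifnot(rise > 0, fall > 0, peak_time - rise >= 0, peak_time + fall <= 100,
            peak_torque >= 0, mass > 0)
  structure(list(peak_time = peak_time, rise = rise, fall = fall,
                 peak_torque = peak_torque, mass = mass,
                 onset = peak_time - rise, end = peak_time + fall),
            class = "exo_profile_params")
}

#' Evaluate the torque profile
#'
#' Two cubic Hermite segments (onset to peak, peak to end) with zero slope
#' at onset, peak and end: C1 everywhere, zero outside the window, equal to
#' the peak magnitude at the peak time, nonnegative.
#'
#' @param t_pct time(s) in % gait cycle (vectorized).
#' @param params an \code{exo_profile_params}.
#' @return torque per unit body mass, N m kg^-1.
#' @export
profile_value <- function(t_pct, params) {
  s <- numeric(length(t_pct))
  up <- t_pct > params$onset & t_pct <= params$peak_time
  dn <- t_pct > params$peak_time & t_pct < params$end
  s[up] <- (t_pct[up] - params$onset) / params$rise
  s[dn] <- (t_pct[dn] - params$end) / (params$peak_time - params$end)
  params$peak_torque * s^2 * (3 - 2 * s)
}

#' The five exoskeleton devices
#'
#' \code{PF} applies a plantarflexion torque across the ankle (equal and
#' opposite body torques on tibia and talus); \code{EV} and \code{INV} apply
#' eversion / inversion torque across the subtalar joint (talus and
#' calcaneus); \code{PF+EV} and \code{PF+INV} combine both. Signs follow the
#' package conventions: plantarflexion drives the ankle coordinate negative,
#' inversion drives the subtalar coordinate positive.
#'
#' @param id one of "PF", "EV", "INV", "PF+EV", "PF+INV".
#' @param side leg the device is mounted on ("r" default).
#' @return list of actuated joints with signs.
#' @export
exo_device <- function(id = c("PF", "EV", "INV", "PF+EV", "PF+INV"),
                       side = "r") {
  id <- match.arg(id)
  ankle <- paste0("ankle_", side); subtalar <- paste0("subtalar_", side)
  joints <- switch(id,
    "PF" = list(list(coord = ankle, sign = -1)),
    "EV" = list(list(coord = subtalar, sign = -1)),
    "INV" = list(list(coord = subtalar, sign = +1)),
    "PF+EV" = list(list(coord = ankle, sign = -1),
                   list(coord = subtalar, sign = -1)),
    "PF+INV" = list(list(coord = ankle, sign = -1),
                    list(coord = subtalar, sign = +1)))
  structure(list(id = id, side = side, joints = joints), class = "exo_device")
}

#' All device identifiers
#' @export
exo_device_ids <- function() c("PF", "EV", "INV", "PF+EV", "PF+INV")

#' Equal-and-opposite body torque pairs for a device
#'
#' For each actuated joint, returns the torque pair applied across it: plus
#' and minus the torque vector (magnitude times the joint's instantaneous
#' axis in the ground frame, times the device sign) on the joint's child and
#' parent bodies. Each pair sums to zero, so device torques never change the
#' net external wrench on the model.
#'
#' @param device an \code{exo_device}.
#' @param magnitude torque magnitude, N m.
#' @inheritParams forward_dynamics
#' @return list per actuated joint: \code{child}, \code{parent} body names
#'   and their torque 3-vectors (world frame).
#' @export
device_body_torques <- function(device, magnitude, model, state) {
  stopifnot(inherits(device, "exo_device"), is.finite(magnitude))
  K <- cpp_fk(model$ptr, state$q, state$u)
  lapply(device$joints, function(j) {
    ji <- coord_index(model, j$coord)
    pidx <- model$flat$parent[ji] + 1L
    # world axis of the pin joint = parent rotation * local axis
    Rp <- if (pidx >= 1) K$R[, , pidx] else diag(3)
    axis_w <- as.numeric(Rp %*% model$flat$axis[, ji])
    tq <- j$sign * magnitude * axis_w
    list(joint = j$coord,
         child = model$body_names[ji], child_torque = tq,
         parent = if (pidx >= 1) model$body_names[pidx] else "ground",
         parent_torque = -tq)
  })
}

#' Enumerate the simulation condition grid
#'
#' Device-major, then peak time ascending, then mode: 5 devices x 9 peak
#' times (20 to 60 %GC by 5) x up to 2 muscle-representation modes.
#'
#' @param include_modes character subset of
#'   \code{c("muscle_driven", "torque_driven")}.
#' @param devices device identifiers.
#' @param peak_times %GC values.
#' @param peak_torque peak magnitude, N m kg^-1.
#' @return data frame, one row per condition.
#' @export
enumerate_conditions <- function(include_modes = c("muscle_driven",
                                                   "torque_driven"),
                                 devices = exo_device_ids(),
                                 peak_times = seq(20, 60, by = 5),
                                 peak_torque = 0.1) {
  stopifnot(all(include_modes %in% c("muscle_driven", "torque_driven")))
  grid <- expand.grid(mode = include_modes, peak_time = peak_times,
                      device = devices, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("device", "peak_time", "mode")]
  grid <- grid[order(match(grid$device, devices), grid$peak_time,
                     match(grid$mode, include_modes)), ]
  rownames(grid) <- NULL
  grid$peak_torque <- peak_torque
  grid$key <- sprintf("%s_p%02d_%s_m%s", gsub("\\+", "", grid$device),
                      grid$peak_time, substr(grid$mode, 1, 1),
                      format(grid$peak_torque))
  grid
}
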