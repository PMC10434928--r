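# Static optimization of muscle excitations along the reference gait, and
# assembly of the full reference (states, controls, GRFs, events). The
# quasi-static solve (activation = excitation) distributes the inverse-
# dynamics moments at muscle-dominant coordinates over the muscles by
# minimizing the sum of squared excitations; residual actuators cover all
# remaining demand and are reported.

# coordinates whose inverse-dynamics moment must be met by muscles
muscle_constrained_coords <- function(model) {
  intersect(c("hip_flexion_r", "knee_r", "ankle_r", "subtalar_r",
              "hip_flexion_l", "knee_l", "ankle_l", "subtalar_l"),
            model$coord_names)
}

# min sum(e^2) s.t. B e = d, 0 <= e <= 1; small active-set on the bounds
solve_effort_qp <- function(B, d, max_iter = 50) {
  nm <- ncol(B)
  e <- rep(0, nm); fixed <- rep(NA_real_, nm)
  flagged <- FALSE
  for (it in seq_len(max_iter)) {
    free <- is.na(fixed)
    dd <- d - if (any(!free)) B[, !free, drop = FALSE] %*% fixed[!free] else 0
    Bf <- B[, free, drop = FALSE]
    sol <- tryCatch({
      G <- Bf %*% t(Bf)
      as.numeric(t(Bf) %*% solve(G + diag(1e-10, nrow(G)), dd))
    }, error = function(err) NULL)
    if (is.null(sol)) { flagged <- TRUE; sol <- rep(0, sum(free)) }
    e[free] <- sol; e[!free] <- fixed[!free]
    out_lo <- free & e < -1e-12
    out_hi <- free & e > 1 + 1e-12
    if (!any(out_lo) && !any(out_hi)) break
    fixed[out_lo] <- 0; fixed[out_hi] <- 1
  }
  e <- pmin(pmax(e, 0), 1)
  resid <- as.numeric(d - B %*% e)
  list(e = e, resid = resid,
       flagged = flagged || max(abs(resid)) > 1e-6 * (1 + max(abs(d))))
}

#' Static optimization of muscle excitations
#'
#' At each node of the gait trajectory, solves min sum(e^2) subject to the
#' muscle moments matching the inverse-dynamics moments at the
#' muscle-constrained coordinates (hip flexion, knee, ankle, subtalar on
#' both legs), with 0 <= e <= 1, activation = excitation (quasi-static) and
#' rigid-tendon force generation linearized in the excitations. Nodes where
#' the demand exceeds muscle capacity fall back to a bound-clipped
#' least-squares solution and are flagged. Residual actuator moments at all
#' coordinates are computed and reported.
#'
#' @param model an \code{exo_model}.
#' @param q,u,udot DOF x N trajectory matrices.
#' @return list: \code{e} (muscles x N excitations), \code{tau_req} (DOF x
#'   N required applied generalized forces; the residual actuator demand at
#'   any coordinate is \code{tau_req} minus the muscle and passive
#'   contributions, computed by [assemble_reference()]), \code{flagged}
#'   node indices where the bound-clipped fallback was used.
#' @export
static_optimization_excitations <- function(model, q, u, udot) {
  N <- ncol(q)
  nm <- model$n_muscles
  mus <- model$flat$muscles
  cons <- muscle_constrained_coords(model)
  ci <- coord_index(model, cons)

  ref <- cpp_reference_batch(model$ptr, q, u, udot)
  E <- matrix(0, nm, N, dimnames = list(model$muscle_names, NULL))
  flagged <- integer(0)

  for (n in seq_len(N)) {
    g <- cpp_muscle_geometry(model$ptr, q[, n], u[, n])
    pass <- cpp_passive_forces(model$ptr, q[, n], u[, n])[, 4]
    # linearize rigid-tendon force: F = e * A + P
    A <- numeric(nm); P <- numeric(nm)
    for (m in seq_len(nm)) {
      mu <- mus[[m]]
      h <- mu$lopt * sin(mu$alpha)
      proj <- max(g$lmt[m] - mu$lts, 0.01 * mu$lopt)
      lM <- sqrt(proj^2 + h^2)
      cosa <- proj / lM
      ltil <- lM / mu$lopt
      vtil <- cosa * g$vmt[m] / (mu$vmax * mu$lopt)
      A[m] <- mu$fiso * cpp_fal(ltil) * cpp_fv(vtil) * cosa
      P[m] <- mu$fiso * cpp_fpe(ltil) * cosa
    }
    demand <- ref$tau_req[ci, n] - pass[ci] -
      as.numeric(t(g$arms[, ci, drop = FALSE]) %*% P)
    B <- t(g$arms[, ci, drop = FALSE] * A)
    sol <- solve_effort_qp(B, demand)
    E[, n] <- sol$e
    if (sol$flagged) flagged <- c(flagged, n)
  }
  list(e = E, tau_req = ref$tau_req, flagged = flagged)
}

#' Assemble the full reference gait
#'
#' Produces the object consumed by the perturbation engine: a 1 kHz grid
#' over one cycle with coordinate values/speeds, muscle activations,
#' excitations (from inverting the activation dynamics so the forward model
#' reproduces the optimized activations), normalized tendon forces of the
#' compliant muscles (isometric equilibrium), residual actuator moments at
#' every coordinate (so forward dynamics reproduces the reference
#' accelerations exactly at the nodes), prescribed muscle moments for the
#' torque-driven mode, per-foot GRFs and COPs, gait events, and scalars
#' (cycle duration, speed, COM height, mass).
#'
#' @param model an \code{exo_model}.
#' @param fit an \code{exo_gait_fit} from [synth_joint_trajectories()].
#' @param dt table resolution, s.
#' @param check_consistency integrate 5 ms from a few nodes and report the
#'   state discrepancy (reported, not enforced).
#' @param act_harmonics harmonics kept when smoothing the nodal activations
#'   into periodic trajectories (lower values band-limit the reference for
#'   coarse-mesh tracking runs).
#' @return object of class \code{exo_reference}.
#' @export
assemble_reference <- function(model, fit, dt = 0.001,
                               check_consistency = TRUE,
                               act_harmonics = 20) {
  Tc <- fit$T
  time <- seq(0, Tc, by = dt)
  if (abs(time[length(time)] - Tc) > 1e-12) time <- c(time, Tc)
  tr <- eval_gait(fit, time)
  nm <- model$n_muscles
  nft <- model$n_ft
  mus <- model$flat$muscles

  # static optimization on a coarser node set, then smooth activations
  sub <- seq(1, length(time) - 1, by = 5)
  so <- static_optimization_excitations(model, tr$q[, sub, drop = FALSE],
                                        tr$u[, sub, drop = FALSE],
                                        tr$udot[, sub, drop = FALSE])
  # Smooth the nodal static-optimization excitations into periodic
  # band-limited excitation trajectories (softplus floor: strictly positive,
  # no clamp kinks), then integrate the activation ODE along them so the
  # stored activations are exactly consistent with their own dynamics.
  # Static optimization assumed activation = excitation; the difference is
  # absorbed by the residual actuators computed below.
  Ns <- length(sub)
  Hh <- min(act_harmonics, floor((Ns - 1) / 2))
  afit <- apply(so$e, 1, function(y) {
    f <- stats::fft(y) / Ns
    c(Re(f[1]), 2 * Re(f[2:(Hh + 1)]), -2 * Im(f[2:(Hh + 1)]))
  })
  w <- 2 * pi / Tc
  E <- matrix(0, nm, length(time))
  for (h in seq_len(Hh)) {
    ch <- cos(h * w * time); sh <- sin(h * w * time)
    E <- E + outer(afit[1 + h, ], ch) + outer(afit[1 + Hh + h, ], sh)
  }
  E <- E + afit[1, ]
  ksoft <- 50
  E <- 1e-3 + log1p(exp(pmin(ksoft * (E - 1e-3), 30))) / ksoft
  E <- pmin(E, 1)
  rownames(E) <- model$muscle_names

  A <- matrix(0, nm, length(time), dimnames = dimnames(E))
  for (m in seq_len(nm)) {
    A[m, ] <- as.numeric(cpp_integrate_activation(
      E[m, ], mus[[m]]$tact, mus[[m]]$tdeact, dt, E[m, 1], 3L))
  }

  # compliant-tendon states: start from the isometric equilibrium at cycle
  # begin, then integrate the tendon-force ODE along the reference for a few
  # cycles so the stored trajectory satisfies its own dynamics (this keeps
  # the collocation defects of the tracking guess at quadrature-error level
  # and minimizes drift in the forward windows)
  FT <- matrix(0, max(nft, 1), length(time))
  ftnames <- character(0)
  if (nft > 0) {
    LMT <- matrix(0, nm, length(time)); VMT <- LMT
    for (n in seq_along(time)) {
      g <- cpp_muscle_geometry(model$ptr, tr$q[, n], tr$u[, n])
      LMT[, n] <- g$lmt; VMT[, n] <- g$vmt
    }
    k <- 0
    for (m in seq_len(nm)) {
      mu <- mus[[m]]
      if (!is.finite(mu$eps0)) next
      k <- k + 1
      ftnames <- c(ftnames, mu$name)
      ft0 <- cpp_tendon_equilibrium(mu$fiso, mu$lopt, mu$lts, mu$alpha,
                                    mu$eps0, A[m, 1], LMT[m, 1])
      FT[k, ] <- as.numeric(cpp_integrate_tendon(
        mu$fiso, mu$lopt, mu$lts, mu$alpha, mu$eps0, mu$vmax,
        A[m, ], LMT[m, ], VMT[m, ], dt, ft0, 3L))
    }
    rownames(FT) <- ftnames
  }

  # residuals: required forces minus muscle minus passive, on the fine grid
  mp <- cpp_muscle_passive_batch(model$ptr, tr$q, tr$u, A,
                                 FT[seq_len(max(nft, 1)), , drop = FALSE])
  ref <- cpp_reference_batch(model$ptr, tr$q, tr$u, tr$udot)
  RES <- ref$tau_req - mp$tau_muscle - mp$tau_passive
  rownames(RES) <- model$coord_names
  PM <- mp$tau_muscle
  rownames(PM) <- model$coord_names

  if (max(ref$foot_force[2, ], ref$foot_force[5, ]) < 10)
    stop("reference has no ground contact; events undetectable")

  # events from the right foot sphere forces
  rsph <- which(model$sphere_foot == 0)
  ev <- detect_gait_events(time, t(ref$sphere_fy[rsph, , drop = FALSE]),
                           model$sphere_group[rsph],
                           total_fy = ref$foot_force[2, ],
                           cop_z_left = ref$cop[6, ],
                           cop_z_right = ref$cop[3, ])

  grf_peak_bw <- max(ref$foot_force[2, ]) / (model$total_mass * 9.81)

  out <- list(
    time = time, dt = dt, T = Tc, speed = fit$params$speed,
    mass = model$total_mass,
    q = tr$q, u = tr$u, udot = tr$udot,
    e = E, a = A, ft = FT, res = RES, pm = PM,
    grf_r = t(ref$foot_force[1:3, , drop = FALSE]),
    grf_l = t(ref$foot_force[4:6, , drop = FALSE]),
    cop_r = t(ref$cop[1:3, , drop = FALSE]),
    cop_l = t(ref$cop[4:6, , drop = FALSE]),
    com_pos = t(ref$com_pos), com_vel = t(ref$com_vel),
    wbam = t(ref$wbam),
    sphere_fy = ref$sphere_fy,
    events = ev, h_com = mean(ref$com_pos[2, ]),
    grf_peak_bw = grf_peak_bw,
    static_opt_flagged = so$flagged,
    gait_fit = fit, model_spec = model$spec)
  class(out) <- "exo_reference"

  if (check_consistency) {
    out$consistency <- reference_consistency(model, out)
  }
  out
}

#' @export
print.exo_reference <- function(x, ...) {
  cat("<exo_reference> cycle ", x$T, " s at ", x$speed, " m/s; h_COM ",
      round(x$h_com, 3), " m; events (%GC): foot-flat ",
      round(x$events$foot_flat, 1), ", heel-off ", round(x$events$heel_off, 1),
      ", toe-off ", round(x$events$toe_off, 1), "; step width ",
      round(x$events$step_width, 3), " m; peak vGRF ",
      round(x$grf_peak_bw, 2), " BW\n", sep = "")
  invisible(x)
}

# short-horizon forward consistency: integrate 5 ms from a few nodes with
# the stored controls and compare against the stored states
reference_consistency <- function(model, ref, horizon = 0.005,
                                  starts = seq(0.05, 0.95, by = 0.15)) {
  ctrl <- reference_controls(ref)
  exo0 <- list(t_on = 0, t_peak = 0.5, t_end = 1, peak = 0,
               joints = integer(0), signs = numeric(0))
  nq <- model$ndof
  errs <- vapply(starts, function(s0) {
    t0 <- s0 * ref$T
    i0 <- which.min(abs(ref$time - t0)); t0 <- ref$time[i0]
    y0 <- c(ref$q[, i0], ref$u[, i0], ref$a[, i0],
            if (model$n_ft > 0) ref$ft[, i0])
    tr <- cpp_integrate_window(model$ptr, y0, t0, t0 + horizon, ctrl, 0L,
                               exo0, 1e-6, 1e-6, horizon, 200000L)
    i1 <- which.min(abs(ref$time - (t0 + horizon)))
    yend <- tr$Y[, ncol(tr$Y)]
    c(max(abs(yend[1:nq] - ref$q[, i1])),
      max(abs(yend[(nq + 1):(2 * nq)] - ref$u[, i1])))
  }, numeric(2))
  list(max_q_err = max(errs[1, ]), max_u_err = max(errs[2, ]),
       per_start = errs)
}

# control tables in the layout the compiled integrator expects
reference_controls <- function(ref, torque_driven = FALSE) {
  list(t0 = 0, dt = ref$dt, e = t(ref$e), res = t(ref$res),
       pm = if (torque_driven) t(ref$pm) else NULL)
}

#' Add periodic band-limited observation noise
#'
#' Adds seeded periodic Gaussian noise (sum of 20 harmonics) to the
#' coordinate trajectories and proportional noise to the stored GRFs,
#' emulating pseudo-experimental tracking inputs. Periodicity is preserved
#' exactly; sigma_q = 0 returns the input unchanged.
#'
#' @param ref an \code{exo_reference}.
#' @param sigma_q target RMS coordinate noise, rad (or m).
#' @param seed integer seed.
#' @param sigma_grf_rel relative GRF noise.
#' @export
add_observation_noise <- function(ref, sigma_q, seed = 1L,
                                  sigma_grf_rel = sigma_q) {
  stopifnot(sigma_q >= 0)
  if (sigma_q == 0 && sigma_grf_rel == 0) return(ref)
  set.seed(seed)
  nh <- 20
  w <- 2 * pi / ref$T
  noisy <- ref
  for (j in seq_len(nrow(ref$q))) {
    a <- rnorm(nh); b <- rnorm(nh)
    nse <- rep(0, length(ref$time))
    for (h in seq_len(nh))
      nse <- nse + a[h] * cos(h * w * ref$time) + b[h] * sin(h * w * ref$time)
    nse <- nse * sigma_q / sqrt(sum(a^2 + b^2) / 2)
    noisy$q[j, ] <- ref$q[j, ] + nse
  }
  if (sigma_grf_rel > 0) {
    for (nmgrf in c("grf_r", "grf_l")) {
      g <- ref[[nmgrf]]
      a <- rnorm(nh); b <- rnorm(nh)
      nse <- rep(0, length(ref$time))
      for (h in seq_len(nh))
        nse <- nse + a[h] * cos(h * w * ref$time) + b[h] * sin(h * w * ref$time)
      nse <- nse / sqrt(sum(a^2 + b^2) / 2)
      noisy[[nmgrf]] <- g * (1 + sigma_grf_rel * nse)
    }
  }
  noisy
}
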