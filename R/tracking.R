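# Direct-collocation tracking stage: turns (pseudo-)experimental kinematics
# and GRFs into a dynamically consistent periodic gait. Hermite-Simpson
# transcription with explicit skeletal and muscle dynamics; the nonlinear
# program is solved by a damped Gauss-Newton (Levenberg-Marquardt) method on
# the stacked weighted residuals, with equality constraints (collocation
# defects, periodicity, average speed) handled by a ramped quadratic
# penalty. The Jacobian is estimated by finite differences with node
# coloring, exploiting the block structure of the transcription.

#' Shift treadmill kinematics to overground
#'
#' Adds belt speed times elapsed time to the fore-aft pelvis coordinate;
#' all other coordinates are unchanged.
#'
#' @param q DOF x N coordinate matrix with a \code{pelvis_tx} row.
#' @param time time grid, s.
#' @param belt_speed treadmill belt speed, m/s.
#' @param t0 reference time subtracted before scaling.
#' @export
treadmill_to_overground <- function(q, time, belt_speed, t0 = time[1]) {
  if (!"pelvis_tx" %in% rownames(q)) stop("fore-aft pelvis coordinate missing")
  q["pelvis_tx", ] <- q["pelvis_tx", ] + belt_speed * (time - t0)
  q
}

#' Default tracking cost weights
#'
#' Squared-error weights for the multi-objective tracking cost: muscle
#' excitation effort, residual-actuator effort (heavy, to discourage
#' hand-of-god forces), coordinate value/speed tracking, GRF tracking, and
#' torso / calcaneus orientation and angular-velocity tracking. Subtalar
#' and MTP coordinates carry zero tracking weight.
#' @export
tracking_weights <- function() {
  list(effort_e = 0.3, effort_res = 0.02,
       q = 5, u = 0.5, grf = 0.002,
       torso = 5, torso_w = 0.2, calcn = 2, calcn_w = 0.1,
       feet_dist = 10, feet_min_dist = 0.10)
}

#' Build the tracking optimal-control problem
#'
#' States: coordinate values and speeds, muscle activations and normalized
#' tendon forces; controls: muscle excitations and residual generalized
#' forces. Integral cost: weighted squared tracking errors (coordinates,
#' speeds, GRFs, torso and calcaneus body orientation/angular velocity)
#' plus weighted squared controls. Constraints: periodicity of all states
#' and controls (the fore-aft pelvis coordinate is constrained through the
#' average-speed equality instead), and a minimum distance between the feet.
#'
#' @param model an \code{exo_model}.
#' @param observations an \code{exo_reference} (possibly noisy) spanning
#'   exactly one cycle.
#' @param weights see [tracking_weights()].
#' @return list of class \code{exo_ocp}.
#' @export
build_tracking_problem <- function(model, observations,
                                   weights = tracking_weights()) {
  stopifnot(all(vapply(weights, function(w) all(w >= 0), TRUE)))
  if (max(weights$q, weights$u, weights$grf, weights$torso, weights$calcn) <= 0)
    stop("at least one tracking weight must be positive")
  obs <- observations
  if (abs(obs$time[length(obs$time)] - obs$time[1] - obs$T) > 1e-6)
    stop("observations must span exactly one gait cycle")
  nq <- model$ndof; nm <- model$n_muscles; nft <- model$n_ft
  nx <- 2 * nq + nm + nft
  nu <- nm + nq
  zero_track <- grepl("^(subtalar|mtp)", model$coord_names)
  wq <- rep(weights$q, nq); wq[zero_track] <- 0
  wu <- rep(weights$u, nq); wu[zero_track] <- 0
  ocp <- list(model = model, obs = obs, weights = weights,
              nx = nx, nu = nu, nq = nq, nm = nm, nft = nft,
              wq = wq, wu = wu,
              n_periodicity = (nx - 1) + nu + 1,  # all but tx, + speed eq
              speed = obs$speed, T = obs$T)
  class(ocp) <- "exo_ocp"
  ocp
}

#' Transcribe with Hermite-Simpson collocation
#'
#' Decision variables are the states and controls at every mesh point and
#' mesh midpoint. Each mesh interval contributes a Hermite (midpoint
#' interpolation) defect and a Simpson (integral) defect, both enforced on
#' the explicit dynamics.
#'
#' @param ocp an \code{exo_ocp} (or a toy problem list with fields
#'   \code{nx}, \code{nu}, \code{T}, \code{f_batch}, \code{node_resid},
#'   \code{global_resid}, \code{guess}).
#' @param mesh_interval mesh spacing, s (10 ms in the reference setup;
#'   coarser meshes are permitted for scaled-down runs).
#' @return list of class \code{exo_nlp}.
#' @export
transcribe_hermite_simpson <- function(ocp, mesh_interval = 0.01) {
  Tc <- ocp$T
  N <- round(Tc / mesh_interval)
  if (abs(N * mesh_interval - Tc) > mesh_interval)
    stop("mesh interval does not divide the cycle duration")
  h <- Tc / N
  nn <- 2 * N + 1
  times <- seq(0, Tc, length.out = nn)
  nlp <- list(ocp = ocp, N = N, h = h, nn = nn, times = times,
              nx = ocp$nx, nu = ocp$nu)
  class(nlp) <- "exo_nlp"
  nlp
}

# interpolate observation tables at arbitrary times (tables are stored
# variables x time, except GRF/COP tables which are time x component)
.obs_at <- function(obs, what, times) {
  X <- obs[[what]]
  if (is.matrix(X) && what %in% c("grf_r", "grf_l", "cop_r", "cop_l"))
    X <- t(X)
  vapply(times, function(t) {
    i <- approx(obs$time, seq_along(obs$time), xout = t, rule = 2)$y
    lo <- floor(i); hi <- ceiling(i); w <- i - lo
    if (is.matrix(X)) (1 - w) * X[, lo] + w * X[, hi]
    else (1 - w) * X[lo] + w * X[hi]
  }, numeric(if (is.matrix(X)) nrow(X) else 1))
}

# walking-problem residual machinery ---------------------------------------

.walk_batch <- function(model, times, X, U) {
  nq <- model$ndof; nm <- model$n_muscles
  E <- t(U[seq_len(nm), , drop = FALSE])
  RES <- t(U[nm + seq_len(nq), , drop = FALSE])
  out <- cpp_rhs_batch(model$ptr, times, X, E, RES)
  list(F = out$ydot, grf = out$grf)
}

# precompute everything about the observations at the node times (targets
# and their body kinematics); done once per solve
.walk_obs_cache <- function(ocp, times) {
  model <- ocp$model
  obs <- ocp$obs
  nn <- length(times)
  qobs <- .obs_at(obs, "q", times); uobs <- .obs_at(obs, "u", times)
  grf_obs <- rbind(.obs_at(obs, "grf_r", times),
                   .obs_at(obs, "grf_l", times))
  tor_i <- body_index(model, "torso")
  cal_r <- body_index(model, "calcn_r"); cal_l <- body_index(model, "calcn_l")
  Ro <- array(0, c(3, 3, 3, nn)); Wo <- array(0, c(3, 3, nn))
  for (n in seq_len(nn)) {
    Ko <- cpp_fk(model$ptr, qobs[, n], uobs[, n])
    for (b in 1:3) {
      bi <- c(tor_i, cal_r, cal_l)[b]
      Ro[, , b, n] <- Ko$R[, , bi]
      Wo[, b, n] <- Ko$w[, bi]
    }
  }
  list(qobs = qobs, uobs = uobs, grf_obs = grf_obs,
       bodies = c(tor_i, cal_r, cal_l), Ro = Ro, Wo = Wo)
}

.walk_node_resid <- function(ocp, times, X, U, extra, cache) {
  model <- ocp$model; w <- ocp$weights
  nq <- ocp$nq; nm <- ocp$nm
  nn <- ncol(X)
  bi <- cache$bodies
  out <- vector("list", nn)
  for (n in seq_len(nn)) {
    q <- X[seq_len(nq), n]; u <- X[nq + seq_len(nq), n]
    K <- cpp_fk(model$ptr, q, u)
    rot_err <- function(b) rotvec_from_matrix(K$R[, , bi[b]] %*% t(cache$Ro[, , b, n]))
    wdiff <- function(b) K$w[, bi[b]] - cache$Wo[, b, n]
    feet <- sqrt(sum((K$p[, bi[2]] - K$p[, bi[3]])^2))
    out[[n]] <- c(
      ocp$wq * (q - cache$qobs[, n]),
      ocp$wu * (u - cache$uobs[, n]),
      w$grf * (extra$grf[n, ] - cache$grf_obs[, n]),
      w$torso * rot_err(1), w$torso_w * wdiff(1),
      w$calcn * c(rot_err(2), rot_err(3)),
      w$calcn_w * c(wdiff(2), wdiff(3)),
      w$effort_e * U[seq_len(nm), n],
      w$effort_res * U[nm + seq_len(nq), n],
      w$feet_dist * max(0, w$feet_min_dist - feet))
  }
  do.call(cbind, out)
}

.walk_global_resid <- function(ocp, X, U, rho) {
  nq <- ocp$nq
  tx <- 1L  # pelvis_tx is the first coordinate
  per_x <- (X[, 1] - X[, ncol(X)])[-tx]
  per_u <- U[, 1] - U[, ncol(U)]
  speed <- (X[tx, ncol(X)] - X[tx, 1]) / ocp$T - ocp$speed
  rho * c(per_x, per_u, speed)
}

# stack all residuals; returns vector + bookkeeping for coloring
.nlp_residual <- function(nlp, Z, rho, layout) {
  ocp <- nlp$ocp
  X <- matrix(Z[seq_len(nlp$nx * nlp$nn)], nlp$nx, nlp$nn)
  U <- matrix(Z[nlp$nx * nlp$nn + seq_len(nlp$nu * nlp$nn)], nlp$nu, nlp$nn)
  be <- if (!is.null(ocp$model)) .walk_batch(ocp$model, nlp$times, X, U)
        else ocp$f_batch(nlp$times, X, U)
  F <- be$F
  N <- nlp$N; h <- nlp$h
  a <- 2 * seq_len(N) - 1; m <- a + 1; b <- a + 2
  herm <- X[, m, drop = FALSE] - 0.5 * (X[, a, drop = FALSE] + X[, b, drop = FALSE]) -
    (h / 8) * (F[, a, drop = FALSE] - F[, b, drop = FALSE])
  simp <- X[, b, drop = FALSE] - X[, a, drop = FALSE] -
    (h / 6) * (F[, a, drop = FALSE] + 4 * F[, m, drop = FALSE] + F[, b, drop = FALSE])
  defects <- rho * rbind(herm, simp)
  if (!is.null(ocp$model) && is.null(nlp$obs_cache))
    nlp$obs_cache <- .walk_obs_cache(ocp, nlp$times)
  noder <- if (!is.null(ocp$model))
    .walk_node_resid(ocp, nlp$times, X, U, be, nlp$obs_cache)
  else ocp$node_resid(nlp$times, X, U, be)
  glob <- if (!is.null(ocp$model)) .walk_global_resid(ocp, X, U, rho)
          else ocp$global_resid(X, U, rho)
  r <- c(as.numeric(defects), as.numeric(noder), glob)
  if (!is.null(layout)) return(r)
  # layout: row ranges for coloring
  ndef <- length(defects); nnod <- length(noder)
  list(r = r,
       layout = list(ndef = ndef, def_per_int = 2 * nlp$nx,
                     nnod = nnod, nod_per_node = nrow(noder),
                     nglob = length(glob)))
}

# rows affected by perturbing any variable at node n: interval i spans
# nodes {2i-1, 2i, 2i+1}; midpoints belong to one interval, mesh points to
# (up to) two
.rows_for_node <- function(nlp, lay, n) {
  N <- nlp$N
  ints <- if (n %% 2 == 0) (n %/% 2) else c((n - 1) %/% 2, (n - 1) %/% 2 + 1)
  ints <- ints[ints >= 1 & ints <= N]
  def_rows <- unlist(lapply(ints, function(i)
    (i - 1) * lay$def_per_int + seq_len(lay$def_per_int)))
  nod_rows <- lay$ndef + (n - 1) * lay$nod_per_node + seq_len(lay$nod_per_node)
  glob_rows <- if (n == 1 || n == nlp$nn)
    lay$ndef + lay$nnod + seq_len(lay$nglob) else integer(0)
  c(def_rows, nod_rows, glob_rows)
}

#' Solve the tracking NLP
#'
#' Damped Gauss-Newton on the stacked weighted residuals with a ramped
#' quadratic penalty on the equality constraints. The initial guess is the
#' observations with excitations from static optimization (for the walking
#' problem, passed via \code{guess}). Deterministic for identical inputs.
#'
#' @param nlp an \code{exo_nlp}.
#' @param guess list with matrices \code{X} (states x nodes) and \code{U}
#'   (controls x nodes); for the walking problem build it with
#'   [tracking_initial_guess()].
#' @param constraint_tol maximum allowed equality-constraint violation.
#' @param convergence_tol relative objective-decrease threshold.
#' @param max_iter Gauss-Newton iterations per penalty level.
#' @param rho0 initial penalty weight.
#' @param max_ramps number of ten-fold penalty increases attempted when the
#'   constraint tolerance is not yet met.
#' @param verbose print per-iteration diagnostics.
#' @return list of class \code{exo_tracking_solution}: solution matrices,
#'   objective value, objective history, iterations, maximum constraint
#'   violation.
#' @export
solve_tracking <- function(nlp, guess, constraint_tol = 1e-4,
                           convergence_tol = 1e-2, max_iter = 25,
                           rho0 = 500, max_ramps = 5, verbose = FALSE) {
  Z <- c(as.numeric(guess$X), as.numeric(guess$U))
  nvar <- length(Z)
  if (!is.null(nlp$ocp$model) && is.null(nlp$obs_cache))
    nlp$obs_cache <- .walk_obs_cache(nlp$ocp, nlp$times)
  rho <- rho0
  obj_hist <- numeric(0)
  total_iter <- 0
  viol <- Inf
  for (ramp in seq_len(max_ramps)) {
    first <- .nlp_residual(nlp, Z, rho, NULL)
    lay <- first$layout
    r <- first$r
    lambda <- 1e-3
    J <- NULL
    refresh <- TRUE
    for (it in seq_len(max_iter)) {
      total_iter <- total_iter + 1
      obj <- sum(r^2)
      obj_hist <- c(obj_hist, obj)
      if (verbose) message(sprintf("ramp %d it %d obj %.6g", ramp, it, obj))
      if (refresh || is.null(J)) {
        # the finite-difference Jacobian is the expensive part; it is
        # reused across iterations and refreshed only when progress stalls
        J <- .nlp_jacobian(nlp, Z, rho, lay, r)
        refresh <- FALSE
      }
      g <- as.numeric(Matrix::crossprod(J, r))
      H <- Matrix::crossprod(J)
      # Marquardt scaling: damp proportionally to column curvature, so
      # contact-sensitive coordinates take small steps while benign
      # directions (e.g. midpoint speeds) converge in one shot
      D <- Matrix::Diagonal(nvar, pmax(Matrix::diag(H), 1e-10))
      ok <- FALSE
      for (tries in 1:12) {
        step <- tryCatch(
          as.numeric(Matrix::solve(H + lambda * D, -g)),
          error = function(e) NULL)
        if (!is.null(step)) {
          Znew <- Z + step
          rnew <- .nlp_residual(nlp, Znew, rho, lay)
          pred <- sum((r + as.numeric(J %*% step))^2)
          if (sum(rnew^2) < obj) {
            # poor agreement with the linear model -> refresh J next time
            if (obj - sum(rnew^2) < 0.25 * (obj - pred)) refresh <- TRUE
            Z <- Znew; r <- rnew
            lambda <- max(lambda / 5, 1e-15)
            ok <- TRUE
            break
          }
        }
        lambda <- lambda * 10
      }
      if (!ok) {
        if (!refresh) { refresh <- TRUE; lambda <- lambda / 1e6; next }
        break
      }
      if (obj - sum(r^2) < convergence_tol * max(obj, 1e-12)) break
    }
    viol <- .constraint_violation(nlp, Z, lay, r, rho)
    if (viol <= constraint_tol) break
    rho <- rho * 10
  }
  if (viol > constraint_tol * 50)
    stop(sprintf("tracking solve failed: constraint violation %.3g > %.3g; ",
                 viol, constraint_tol),
         "inspect weights/penalty; last objective ", tail(obj_hist, 1))
  X <- matrix(Z[seq_len(nlp$nx * nlp$nn)], nlp$nx, nlp$nn)
  U <- matrix(Z[nlp$nx * nlp$nn + seq_len(nlp$nu * nlp$nn)], nlp$nu, nlp$nn)
  rfin <- .nlp_residual(nlp, Z, rho, NULL)
  layf <- rfin$layout
  defects <- rfin$r[seq_len(layf$ndef)] / rho
  glob <- rfin$r[layf$ndef + layf$nnod + seq_len(layf$nglob)] / rho
  out <- list(X = X, U = U, times = nlp$times,
              objective = tail(obj_hist, 1), objective_history = obj_hist,
              iterations = total_iter, max_violation = viol,
              max_defect = max(abs(defects)),
              max_periodicity = max(abs(glob)),
              constraint_tol = constraint_tol)
  class(out) <- "exo_tracking_solution"
  out
}

.constraint_violation <- function(nlp, Z, lay, r, rho) {
  defects <- r[seq_len(lay$ndef)] / rho
  glob <- r[lay$ndef + lay$nnod + seq_len(lay$nglob)] / rho
  max(abs(c(defects, glob)))
}

.nlp_jacobian <- function(nlp, Z, rho, lay, r0) {
  nn <- nlp$nn; nx <- nlp$nx; nu <- nlp$nu
  nv_node <- nx + nu
  fdh <- 1e-6
  colors <- ((seq_len(nn) - 1) %% 3) + 1
  colors[1] <- 4; colors[nn] <- 5
  trips_i <- list(); trips_j <- list(); trips_x <- list()
  var_index <- function(n, v) {
    if (v <= nx) (n - 1) * nx + v else nx * nn + (n - 1) * nu + (v - nx)
  }
  rows_cache <- lapply(seq_len(nn), function(n) .rows_for_node(nlp, lay, n))
  for (cl in 1:5) {
    nodes <- which(colors == cl)
    if (!length(nodes)) next
    for (v in seq_len(nv_node)) {
      Zp <- Z
      for (n in nodes) Zp[var_index(n, v)] <- Zp[var_index(n, v)] + fdh
      rp <- .nlp_residual(nlp, Zp, rho, lay)
      dr <- (rp - r0) / fdh
      for (n in nodes) {
        rows <- rows_cache[[n]]
        vals <- dr[rows]
        nzr <- which(vals != 0)
        if (length(nzr)) {
          trips_i[[length(trips_i) + 1]] <- rows[nzr]
          trips_j[[length(trips_j) + 1]] <- rep(var_index(n, v), length(nzr))
          trips_x[[length(trips_x) + 1]] <- vals[nzr]
        }
      }
    }
  }
  Matrix::sparseMatrix(i = unlist(trips_i), j = unlist(trips_j),
                       x = unlist(trips_x),
                       dims = c(length(r0), length(Z)))
}

#' Initial guess for the tracking solve
#'
#' Observations interpolated at the collocation nodes, with activations,
#' tendon forces, excitations and residual moments from the reference
#' tables (static optimization + activation-dynamics inversion).
#'
#' @param ocp an \code{exo_ocp}.
#' @param nlp the transcribed problem.
#' @export
tracking_initial_guess <- function(ocp, nlp) {
  obs <- ocp$obs
  times <- nlp$times
  X <- rbind(.obs_at(obs, "q", times), .obs_at(obs, "u", times),
             .obs_at(obs, "a", times),
             if (ocp$nft > 0) .obs_at(obs, "ft", times))
  U <- rbind(.obs_at(obs, "e", times), .obs_at(obs, "res", times))
  list(X = X, U = U)
}

#' Coordinate recovery error of a tracking solution
#'
#' RMS error per coordinate (rad) between the solved trajectory and a
#' reference, evaluated at the collocation nodes.
#'
#' @param solution an \code{exo_tracking_solution}.
#' @param ref an \code{exo_reference} (the generating truth).
#' @param model the model (for coordinate names).
#' @export
tracking_rms_error <- function(solution, ref, model) {
  nq <- model$ndof
  qsol <- solution$X[seq_len(nq), , drop = FALSE]
  qref <- .obs_at(ref, "q", solution$times)
  rms <- sqrt(rowMeans((qsol - qref)^2))
  setNames(rms, model$coord_names)
}
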