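# Outcome battery: changes in COM kinematics, right-foot COP and whole-body
# angular momentum between exo and baseline trajectories, dimensionless
# normalization (COM height, gravity, Froude velocity scale, foot width),
# exoskeleton power statistics, linearity scans and descriptive summaries.

#' Outcome normalizers
#'
#' COM height (cycle-average of the reference), g, total mass, foot width
#' 0.11 m (distance between the medial and lateral metatarsal contact
#' spheres), and the Froude velocity scale sqrt(g * h_COM). Velocities are
#' divided by the Froude scale (dimensionless Froude number), positions by
#' h_COM, accelerations by g, COP by foot width, and angular momentum by
#' mass * h_COM * sqrt(g * h_COM).
#'
#' @param ref an \code{exo_reference} (or a list with \code{h_com},
#'   \code{mass}).
#' @param foot_width foot width, m.
#' @export
outcome_normalizers <- function(ref, foot_width = 0.11) {
  g <- 9.81
  h <- ref$h_com
  stopifnot(h > 0, ref$mass > 0, foot_width > 0)
  list(h_com = h, g = g, mass = ref$mass, foot_width = foot_width,
       froude_v = sqrt(g * h), wbam = ref$mass * h * sqrt(g * h))
}

.interp_rows <- function(time, X, t) {
  apply(X, 2, function(col) approx(time, col, xout = t, rule = 2)$y)
}

.dir_label <- function(v, pos, neg, tol = 1e-12) {
  ifelse(abs(v) <= tol, "none", ifelse(v > 0, pos, neg))
}

#' Outcome record for one condition
#'
#' Changes are exo minus baseline: COM acceleration and right-foot COP at
#' the peak-torque time; COM velocity, COM position and whole-body angular
#' momentum at the torque end time. Raw and dimensionless values are both
#' reported, with direction labels (forward/backward, up/down,
#' lateral/medial with lateral = +z during right-foot stance).
#'
#' @param pair result of [run_condition()] (or a list with \code{exo},
#'   \code{baseline}, \code{window}, \code{condition}).
#' @param normalizers see [outcome_normalizers()].
#' @return one-row data frame of class \code{exo_outcome}.
#' @export
delta_outcomes <- function(pair, normalizers) {
  exo <- pair$exo; base <- pair$baseline
  if (length(exo$time) != length(base$time) ||
      max(abs(exo$time - base$time)) > 1e-9)
    stop("exo and baseline trajectories have mismatched time grids")
  w <- pair$window; nz <- normalizers
  tp <- w$t_peak; te <- w$t_end

  d_acc <- .interp_rows(exo$time, exo$com_acc, tp) -
    .interp_rows(base$time, base$com_acc, tp)
  d_vel <- .interp_rows(exo$time, exo$com_vel, te) -
    .interp_rows(base$time, base$com_vel, te)
  d_pos <- .interp_rows(exo$time, exo$com_pos, te) -
    .interp_rows(base$time, base$com_pos, te)
  d_wbam <- .interp_rows(exo$time, exo$wbam, te) -
    .interp_rows(base$time, base$wbam, te)

  ip <- which.min(abs(exo$time - tp))
  cop_def <- exo$cop_r_defined[ip] && base$cop_r_defined[ip]
  d_cop <- if (cop_def) {
    .interp_rows(exo$time, exo$cop_r, tp) - .interp_rows(base$time, base$cop_r, tp)
  } else c(NA_real_, NA_real_, NA_real_)

  pw <- exo_power_stats(pair)

  out <- data.frame(
    device = pair$condition$device, peak_time = pair$condition$peak_time,
    mode = pair$condition$mode, peak_torque = pair$condition$peak_torque,
    d_acc_x = d_acc[1], d_acc_y = d_acc[2], d_acc_z = d_acc[3],
    d_vel_x = d_vel[1], d_vel_y = d_vel[2], d_vel_z = d_vel[3],
    d_pos_x = d_pos[1], d_pos_y = d_pos[2], d_pos_z = d_pos[3],
    d_cop_x = d_cop[1], d_cop_z = d_cop[3], cop_defined = cop_def,
    d_wbam_x = d_wbam[1], d_wbam_y = d_wbam[2], d_wbam_z = d_wbam[3],
    pow_pos = pw$mean_positive, pow_neg = pw$mean_negative,
    stringsAsFactors = FALSE)
  # dimensionless companions
  out$d_acc_x_n <- out$d_acc_x / nz$g
  out$d_acc_y_n <- out$d_acc_y / nz$g
  out$d_acc_z_n <- out$d_acc_z / nz$g
  out$d_vel_x_n <- out$d_vel_x / nz$froude_v
  out$d_vel_y_n <- out$d_vel_y / nz$froude_v
  out$d_vel_z_n <- out$d_vel_z / nz$froude_v
  out$d_pos_x_n <- out$d_pos_x / nz$h_com
  out$d_pos_y_n <- out$d_pos_y / nz$h_com
  out$d_pos_z_n <- out$d_pos_z / nz$h_com
  out$d_cop_x_n <- out$d_cop_x / nz$foot_width
  out$d_cop_z_n <- out$d_cop_z / nz$foot_width
  out$d_wbam_x_n <- out$d_wbam_x / nz$wbam
  out$d_wbam_y_n <- out$d_wbam_y / nz$wbam
  out$d_wbam_z_n <- out$d_wbam_z / nz$wbam
  out$label_vel_x <- .dir_label(out$d_vel_x, "forward", "backward")
  out$label_vel_y <- .dir_label(out$d_vel_y, "up", "down")
  out$label_vel_z <- .dir_label(out$d_vel_z, "lateral", "medial")
  class(out) <- c("exo_outcome", class(out))
  out
}

#' Exoskeleton power statistics
#'
#' Instantaneous device power = applied torque x joint angular speed per
#' actuated joint; positive and negative parts are averaged separately over
#' the window and normalized by body mass. For combined devices only the
#' plantarflexion (ankle) component is reported, matching the convention
#' for plantarflexion exoskeleton power.
#'
#' @param pair result of [run_condition()].
#' @param component "pf" (ankle component, default for combined devices) or
#'   "all".
#' @return list: \code{mean_positive}, \code{mean_negative} (W/kg).
#' @export
exo_power_stats <- function(pair, component = "pf") {
  exo <- pair$exo
  dev <- exo_device(pair$condition$device)
  mass <- attr(pair, "mass") %||% NULL
  joints <- vapply(dev$joints, function(j) j$coord, "")
  signs <- vapply(dev$joints, function(j) j$sign, 0)
  if (component == "pf" && length(joints) > 1) {
    keep <- grepl("^ankle", joints)
    joints <- joints[keep]; signs <- signs[keep]
  }
  if (length(joints) == 0) return(list(mean_positive = 0, mean_negative = 0))
  p <- rep(0, length(exo$time))
  for (k in seq_along(joints)) {
    uj <- exo$u[joints[k], ]
    p <- p + signs[k] * exo$exo_torque * uj
  }
  m <- if (!is.null(mass)) mass else NULL
  if (is.null(m)) {
    # peak torque is per unit mass: recover mass from the applied torque
    m <- max(exo$exo_torque) / pair$condition$peak_torque
    if (!is.finite(m) || m <= 0) m <- 1
  }
  list(mean_positive = mean(pmax(p, 0)) / m,
       mean_negative = mean(pmin(p, 0)) / m)
}

#' Linearity of kinematic changes in peak torque
#'
#' Runs a condition at several peak-torque magnitudes and regresses the
#' dimensionless magnitude of the COM position, velocity and acceleration
#' changes against peak torque. A strong linear relationship (R^2 near 1)
#' indicates the response scales with the applied torque.
#'
#' @param model,ref model and reference gait.
#' @param device,peak_time,mode condition.
#' @param magnitudes peak torques, N m kg^-1 (>= 3 values, all <= 0.15; at
#'   0.2 and above joints often hit range-of-motion limits).
#' @param through_origin force the fit through zero.
#' @param cache optional environment.
#' @return data frame: quantity, slope, intercept, r_squared.
#' @export
linearity_scan <- function(model, ref, device = "PF", peak_time = 40,
                           mode = "muscle_driven",
                           magnitudes = c(0.025, 0.05, 0.1),
                           through_origin = FALSE, cache = NULL) {
  stopifnot(length(magnitudes) >= 3, all(magnitudes <= 0.15))
  if (all(magnitudes == 0)) stop("all magnitudes are zero: degenerate scan")
  nz <- outcome_normalizers(ref)
  rows <- lapply(magnitudes, function(mag) {
    pair <- run_condition(model, ref, device, peak_time, mode,
                          peak_torque = mag, cache = cache)
    rec <- delta_outcomes(pair, nz)
    c(pos = sqrt(rec$d_pos_x_n^2 + rec$d_pos_y_n^2 + rec$d_pos_z_n^2),
      vel = sqrt(rec$d_vel_x_n^2 + rec$d_vel_y_n^2 + rec$d_vel_z_n^2),
      acc = sqrt(rec$d_acc_x_n^2 + rec$d_acc_y_n^2 + rec$d_acc_z_n^2))
  })
  M <- do.call(rbind, rows)
  out <- lapply(colnames(M), function(qty) {
    y <- M[, qty]
    fit <- if (through_origin) lm(y ~ 0 + magnitudes) else lm(y ~ magnitudes)
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    data.frame(quantity = qty,
               slope = unname(coef(fit)[length(coef(fit))]),
               intercept = if (through_origin) 0 else unname(coef(fit)[1]),
               r_squared = 1 - ss_res / ss_tot)
  })
  do.call(rbind, out)
}

#' Descriptive summary of outcome records
#'
#' Mean and SD of each outcome by device x peak time x mode, the
#' maximum-magnitude condition per outcome class, and the ratio of each
#' velocity-change magnitude to the walking speed (in percent).
#'
#' @param records data frame of rows from [delta_outcomes()].
#' @param walking_speed m/s, for the velocity ratio column.
#' @param grouping character vector of grouping columns.
#' @return list: \code{by_group} (data frame), \code{maxima} (data frame).
#' @export
summarize_outcomes <- function(records, walking_speed = 1.25,
                               grouping = c("device", "peak_time", "mode")) {
  if (is.null(records) || nrow(records) == 0) stop("no outcome records")
  records$d_vel_mag <- sqrt(records$d_vel_x^2 + records$d_vel_y^2 +
                              records$d_vel_z^2)
  records$vel_ratio_pct <- 100 * records$d_vel_mag / walking_speed
  num <- vapply(records, is.numeric, TRUE)
  num[names(records) %in% grouping] <- FALSE
  agg_mean <- stats::aggregate(records[num], records[grouping], mean)
  agg_sd <- stats::aggregate(records[num], records[grouping], sd)
  classes <- list(vel = "d_vel_mag",
                  acc = c("d_acc_x", "d_acc_y", "d_acc_z"),
                  cop = c("d_cop_x", "d_cop_z"))
  maxima <- do.call(rbind, lapply(names(classes), function(cl) {
    cols <- classes[[cl]]
    mag <- sqrt(rowSums(records[, cols, drop = FALSE]^2))
    i <- which.max(ifelse(is.na(mag), -Inf, mag))
    data.frame(class = cl, value = mag[i],
               device = records$device[i], peak_time = records$peak_time[i],
               mode = records$mode[i],
               vel_ratio_pct = if (cl == "vel") records$vel_ratio_pct[i] else NA)
  }))
  list(by_group = merge(agg_mean, agg_sd, by = grouping,
                        suffixes = c("_mean", "_sd")),
       maxima = maxima)
}
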