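# Model assembly: validate an exo_model_spec, flatten it to the single-DOF
# joint representation used by the compiled core, and wrap the result.

.strip_side <- function(x) sub("_(r|l)$", "", x)

#' Build the reduced walking model
#'
#' Validates a model specification (see [default_model_spec()]) and compiles
#' it into a queryable model object exposing DOF count, mass properties,
#' muscle geometry and contact geometry. The default specification yields 23
#' degrees of freedom: a 6-DOF free pelvis, 3-DOF lumbar, and per leg a
#' 3-DOF hip, knee, ankle, subtalar and MTP joint.
#'
#' @param spec an \code{exo_model_spec}; defaults to the packaged model.
#' @return An object of class \code{exo_model}.
#' @export
build_reduced_model <- function(spec = default_model_spec()) {
  stopifnot(inherits(spec, "exo_model_spec") || is.list(spec))
  validate_model_spec(spec)
  flat <- flatten_model_spec(spec)
  model <- list(
    spec = spec, flat = flat,
    ptr = cpp_model_build(flat),
    ndof = flat$nq,
    coord_names = flat$coord_names,
    body_names = flat$body_names,
    total_mass = sum(flat$mass),
    gravity = flat$gravity,
    muscle_names = vapply(flat$muscles, function(m) m$name, ""),
    n_muscles = length(flat$muscles),
    n_ft = sum(vapply(flat$muscles, function(m) is.finite(m$eps0), TRUE)),
    sphere_foot = flat$spheres$foot,
    sphere_group = flat$spheres$group_name)
  class(model) <- "exo_model"
  model
}

#' @export
print.exo_model <- function(x, ...) {
  cat("<exo_model> ", x$spec$name, ": ", x$ndof, " DOF, ",
      x$n_muscles, " muscles, ", length(x$sphere_foot), " contact spheres, ",
      sprintf("%.1f kg", x$total_mass), "\n", sep = "")
  invisible(x)
}

validate_model_spec <- function(spec) {
  jn <- vapply(spec$joints, function(j) j$name, "")
  if (anyDuplicated(jn)) stop("duplicate joint names: ",
                              paste(jn[duplicated(jn)], collapse = ", "))
  roots <- vapply(spec$joints, function(j) is.na(j$parent[1]), TRUE)
  if (sum(roots) != 1)
    stop("model must have exactly one free (6-DOF) joint chain to ground; ",
         "found ", sum(roots), " root joints")
  # tree rooted at ground: every parent must be an earlier joint
  for (i in seq_along(spec$joints)) {
    j <- spec$joints[[i]]
    if (!is.na(j$parent[1])) {
      k <- match(j$parent, jn)
      if (is.na(k)) stop("joint '", j$name, "' has unknown parent '", j$parent, "'")
      if (k >= i) stop("joint graph is not a tree in topological order near '",
                       j$name, "'")
    }
    ax <- j$axis
    if (abs(sqrt(sum(ax^2)) - 1) > 1e-8)
      stop("joint '", j$name, "' axis is not unit-norm")
    if (diff(j$range) <= 0) stop("joint '", j$name, "' has empty range")
  }
  bn <- vapply(spec$bodies, function(b) b$name, "")
  if (anyDuplicated(bn)) stop("duplicate body names")
  for (b in spec$bodies) {
    if (b$mass < 0) stop("body '", b$name, "' has negative mass")
    if (b$mass > 0 && any(b$inertia <= 0))
      stop("body '", b$name, "' inertia is not positive definite")
  }
  if (spec$total_mass <= 0) stop("total mass must be positive")
  invisible(TRUE)
}

flatten_model_spec <- function(spec) {
  joints <- spec$joints
  jn <- vapply(joints, function(j) j$name, "")
  nq <- length(joints)
  parent <- integer(nq); jtype <- integer(nq)
  axis <- matrix(0, 3, nq); offset <- matrix(0, 3, nq)
  mass <- numeric(nq); com <- matrix(0, 3, nq)
  inertia <- array(0, c(3, 3, nq))
  qmin <- numeric(nq); qmax <- numeric(nq)
  body_names <- character(nq)
  for (i in seq_len(nq)) {
    j <- joints[[i]]
    parent[i] <- if (is.na(j$parent[1])) -1L else match(j$parent, jn) - 1L
    jtype[i] <- if (j$type == "slider") 0L else 1L
    axis[, i] <- j$axis
    offset[, i] <- j$offset
    qmin[i] <- j$range[1]; qmax[i] <- j$range[2]
    if (!is.null(j$body)) {
      b <- spec$bodies[[.strip_side(j$body)]]
      if (is.null(b)) stop("no body template for '", j$body, "'")
      mass[i] <- b$mass
      com[, i] <- b$com
      inertia[, , i] <- diag(pmax(b$inertia, 1e-12), 3)
      body_names[i] <- j$body
    } else {
      inertia[, , i] <- diag(1e-12, 3)
      body_names[i] <- paste0(".dummy_", j$name)
    }
  }
  # rescale masses so the flattened model hits the specified total mass
  msum <- sum(mass)
  if (abs(msum - spec$total_mass) > 1e-9) mass <- mass * spec$total_mass / msum

  passive <- flatten_passive(spec, jn, qmin, qmax)
  muscles <- flatten_muscles(spec, jn)
  spheres <- flatten_spheres(spec, jn, body_names)

  list(nq = nq, parent = parent, jtype = jtype, axis = axis, offset = offset,
       mass = mass, com = com, inertia = inertia,
       coord_names = jn, body_names = body_names,
       qmin = qmin, qmax = qmax, gravity = spec$gravity,
       passive = passive, muscles = muscles, spheres = spheres,
       contact_params = spec$contact)
}

flatten_passive <- function(spec, jn, qmin, qmax) {
  p <- spec$passive
  nq <- length(jn)
  klin <- numeric(nq); q0 <- numeric(nq); damp <- numeric(nq)
  expo_on <- integer(nq)
  for (i in seq_len(nq)) {
    nm <- .strip_side(jn[i])
    if (nm == "lumbar_extension") { klin[i] <- p$lumbar_k[["extension"]]; damp[i] <- p$lumbar_damping }
    else if (nm == "lumbar_bending") { klin[i] <- p$lumbar_k[["bending"]]; damp[i] <- p$lumbar_damping }
    else if (nm == "lumbar_rotation") { klin[i] <- p$lumbar_k[["rotation"]]; damp[i] <- p$lumbar_damping }
    else if (nm == "ankle") { klin[i] <- p$bushing_k; damp[i] <- p$ankle_damping + p$bushing_damping }
    else if (nm == "subtalar") { klin[i] <- p$bushing_k; damp[i] <- p$subtalar_damping + p$bushing_damping }
    else if (nm == "mtp") { klin[i] <- p$mtp_k; damp[i] <- p$mtp_damping }
    else if (nm %in% c("hip_flexion", "hip_adduction", "hip_rotation", "knee"))
      damp[i] <- p$expo_damping
    # range-of-motion guards on all internal rotational coordinates
    expo_on[i] <- as.integer(!(nm %in% c("pelvis_tx", "pelvis_ty", "pelvis_tz",
                                         "pelvis_tilt", "pelvis_list",
                                         "pelvis_rotation")))
  }
  list(klin = klin, q0 = numeric(nq), damp = damp,
       expo_c1 = rep(p$expo_c1, nq), expo_c2 = rep(p$expo_c2, nq),
       qen_lo = qmin + p$expo_margin, qen_hi = qmax - p$expo_margin,
       expo_on = expo_on)
}

# reference posture for anchoring fiber operating lengths: muscles sit on
# the ascending limb (l/lopt = 0.92) of the force-length curve in a
# representative loaded mid-stance configuration, which gives the
# physiological spring-like (stabilizing) length feedback under small
# kinematic perturbations
.muscle_ref_posture <- c(hip_flexion = 0.35, hip_adduction = 0,
                         hip_rotation = 0, knee = 0.25, ankle = 0.08,
                         subtalar = -0.04, mtp = 0)
.muscle_ref_ltilde <- 0.92

flatten_muscles <- function(spec, jn) {
  out <- list()
  for (side in c("r", "l")) {
    for (tpl in spec$muscles) {
      coords <- paste0(tpl$coords, "_", side)
      idx <- match(coords, jn)
      if (anyNA(idx)) stop("muscle '", tpl$name, "' spans unknown coordinate")
      path <- rbind(idx - 1L, tpl$c1, rep(0, length(idx)))
      h <- tpl$lopt * sin(tpl$alpha)
      lref <- .muscle_ref_ltilde * tpl$lopt
      proj <- sqrt(max(lref^2 - h^2, (0.2 * tpl$lopt)^2))
      qref <- .muscle_ref_posture[tpl$coords]
      qref[is.na(qref)] <- 0
      out[[length(out) + 1L]] <- list(
        name = paste0(tpl$name, "_", side),
        fiso = tpl$fiso, lopt = tpl$lopt, lts = tpl$lts, alpha = tpl$alpha,
        eps0 = if (is.na(tpl$eps0)) NA_real_ else tpl$eps0,
        tact = tpl$tact, tdeact = tpl$tdeact, vmax = tpl$vmax,
        L0 = tpl$lts + proj - sum(tpl$c1 * qref),
        path = path)
    }
  }
  out
}

flatten_spheres <- function(spec, jn, body_names) {
  ns <- length(spec$spheres)
  body <- integer(ns); loc <- matrix(0, 3, ns); radius <- numeric(ns)
  foot <- integer(ns); group <- integer(ns); group_name <- character(ns)
  gmap <- c(heel = 0L, mid = 1L, met = 2L, toe = 3L)
  for (s in seq_len(ns)) {
    sp <- spec$spheres[[s]]
    bi <- match(sp$body, body_names)
    if (is.na(bi)) stop("contact sphere attached to unknown body '", sp$body, "'")
    body[s] <- bi - 1L
    loc[, s] <- sp$loc
    radius[s] <- sp$radius
    foot[s] <- if (sp$foot == "r") 0L else 1L
    group[s] <- gmap[[sp$group]]
    group_name[s] <- sp$group
  }
  list(body = body, loc = loc, radius = radius, foot = foot, group = group,
       group_name = group_name)
}

# coordinate index lookup (1-based)
coord_index <- function(model, names) {
  idx <- match(names, model$coord_names)
  if (anyNA(idx)) stop("unknown coordinate(s): ",
                       paste(names[is.na(idx)], collapse = ", "))
  idx
}

body_index <- function(model, names) {
  idx <- match(names, model$body_names)
  if (anyNA(idx)) stop("unknown body(s): ", paste(names[is.na(idx)], collapse = ", "))
  idx
}

# internal: build a model directly from a flat list (used for toy models in
# tests; skips the anatomical spec layer)
build_flat_model <- function(flat) {
  model <- list(
    spec = NULL, flat = flat, ptr = cpp_model_build(flat),
    ndof = flat$nq, coord_names = flat$coord_names,
    body_names = flat$body_names, total_mass = sum(flat$mass),
    gravity = flat$gravity,
    muscle_names = vapply(flat$muscles, function(m) m$name, ""),
    n_muscles = length(flat$muscles),
    n_ft = sum(vapply(flat$muscles, function(m) is.finite(m$eps0), TRUE)),
    sphere_foot = flat$spheres$foot, sphere_group = flat$spheres$group_name)
  class(model) <- "exo_model"
  model
}
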