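# Shared fixtures, built once per test run and cached. Everything is
# generated in code; no data files.

.fix <- new.env(parent = emptyenv())

fix_model <- function() {
  if (is.null(.fix$model)) .fix$model <- build_reduced_model()
  .fix$model
}

fix_gait_fit <- function() {
  if (is.null(.fix$fit))
    .fix$fit <- suppressWarnings(synth_joint_trajectories(gait_params(),
                                                          fix_model()))
  .fix$fit
}

fix_reference <- function() {
  if (is.null(.fix$ref))
    .fix$ref <- assemble_reference(fix_model(), fix_gait_fit(),
                                   check_consistency = FALSE)
  .fix$ref
}

fix_cache <- function() {
  if (is.null(.fix$cache)) .fix$cache <- new.env()
  .fix$cache
}

# full default condition grid (devices x 9 peak times x 2 modes), built on
# demand and reused by the pipeline test and the acceptance criteria
fix_grid_records <- function() {
  if (is.null(.fix$grid)) {
    model <- fix_model(); ref <- fix_reference()
    nz <- outcome_normalizers(ref)
    cache <- fix_cache()
    recs <- list()
    for (dev in exo_device_ids()) for (pt in seq(20, 60, 5))
      for (md in c("muscle_driven", "torque_driven")) {
        pair <- run_condition(model, ref, dev, pt, md, cache = cache)
        recs[[length(recs) + 1]] <- delta_outcomes(pair, nz)
      }
    .fix$grid <- do.call(rbind, recs)
  }
  .fix$grid
}

# single-pin pendulum: mass m at distance lc, inertia I about its COM
toy_pendulum <- function(m = 2, lc = 0.5, Icom = 0.1, damping = 0) {
  flat <- list(
    nq = 1L, parent = -1L, jtype = 1L,
    axis = matrix(c(0, 0, 1)), offset = matrix(c(0, 0, 0)),
    mass = m, com = matrix(c(0, -lc, 0)),
    inertia = array(diag(c(Icom, Icom, Icom)), c(3, 3, 1)),
    coord_names = "pend", body_names = "bob",
    qmin = -10, qmax = 10, gravity = 9.81,
    passive = list(klin = 0, q0 = 0, damp = damping, expo_c1 = 1,
                   expo_c2 = 10, qen_lo = -10, qen_hi = 10, expo_on = 0L),
    muscles = list(), spheres = .no_spheres(),
    contact_params = default_contact_params())
  exowalk:::build_flat_model(flat)
}

# free-flying single body (3 sliders + 3 pins), for flight-phase checks
toy_free_body <- function(m = 5, Idiag = c(0.2, 0.3, 0.4)) {
  flat <- list(
    nq = 6L, parent = as.integer(c(-1, 0, 1, 2, 3, 4)),
    jtype = as.integer(c(0, 0, 0, 1, 1, 1)),
    axis = cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)),
    offset = matrix(0, 3, 6),
    mass = c(0, 0, 0, 0, 0, m),
    com = matrix(0, 3, 6),
    inertia = array(c(rep(diag(1e-12, 3), 5), diag(Idiag)), c(3, 3, 6)),
    coord_names = c("tx", "ty", "tz", "rz", "rx", "ry"),
    body_names = c(paste0(".d", 1:5), "body"),
    qmin = rep(-100, 6), qmax = rep(100, 6), gravity = 9.81,
    passive = list(klin = rep(0, 6), q0 = rep(0, 6), damp = rep(0, 6),
                   expo_c1 = rep(1, 6), expo_c2 = rep(10, 6),
                   qen_lo = rep(-100, 6), qen_hi = rep(100, 6),
                   expo_on = rep(0L, 6)),
    muscles = list(), spheres = .no_spheres(),
    contact_params = default_contact_params())
  exowalk:::build_flat_model(flat)
}

# slider with viscous damper: u' = -(b/m) u, a linear test ODE
toy_damped_slider <- function(m = 1, b = 1) {
  flat <- list(
    nq = 1L, parent = -1L, jtype = 0L,
    axis = matrix(c(1, 0, 0)), offset = matrix(c(0, 0, 0)),
    mass = m, com = matrix(c(0, 0, 0)),
    inertia = array(diag(1e-6, 3), c(3, 3, 1)),
    coord_names = "x", body_names = "cart",
    qmin = -100, qmax = 100, gravity = 0,
    passive = list(klin = 0, q0 = 0, damp = b, expo_c1 = 1, expo_c2 = 10,
                   qen_lo = -100, qen_hi = 100, expo_on = 0L),
    muscles = list(), spheres = .no_spheres(),
    contact_params = default_contact_params())
  exowalk:::build_flat_model(flat)
}

.no_spheres <- function() {
  list(body = integer(0), loc = matrix(0, 3, 0), radius = numeric(0),
       foot = integer(0), group = integer(0), group_name = character(0))
}

no_exo <- function(t0 = 0, t1 = 1) {
  list(t_on = t0, t_peak = (t0 + t1) / 2, t_end = t1, peak = 0,
       joints = integer(0), signs = numeric(0))
}

zero_ctrl <- function(model) {
  list(t0 = 0, dt = 1, e = matrix(0, 1, model$n_muscles),
       res = matrix(0, 1, model$ndof), pm = NULL)
}

soleus_params <- function() {
  tab <- default_muscle_table()
  tab[[which(vapply(tab, function(m) m$name, "") == "soleus")]]
}
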