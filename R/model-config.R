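# Reduced 3D walking model: topology, mass properties, passive elements,
# muscle routing and contact layout. The default numbers target a 1.80 m,
# 72.4 kg adult. All multi-DOF joints are expressed as chains of single-DOF
# pin/slider joints with massless intermediate bodies, which keeps the
# dynamics core uniform.

#' Default reduced walking model specification
#'
#' Builds the packaged 23-DOF model specification: a 6-DOF free pelvis, a
#' lumped torso+head+arms segment behind a 3-DOF lumbar joint, and per leg a
#' 3-DOF hip, 1-DOF knee, ankle, subtalar and metatarsophalangeal (MTP)
#' joint. Twelve Hill-type muscles per leg actuate hip flexion/abduction,
#' knee, ankle and both subtalar directions; six contact spheres per foot
#' carry the smoothed Hunt-Crossley foot-ground contact model.
#'
#' Passive elements follow common practice for tracking simulations of gait:
#' mass-scaled lumbar springs (1.0 / 1.5 / 0.5 N m rad^-1 kg^-1 for
#' extension / bending / rotation), 2 N m s rad^-1 damping at the ankle,
#' lumbar, subtalar and MTP joints, a 25 N m rad^-1 MTP spring, a diagonal
#' ankle-subtalar bushing (10 N m rad^-1, 0.5 N m s rad^-1 per axis), and
#' exponential range-of-motion guard springs that engage 5 degrees inside
#' each coordinate range.
#'
#' @param mass total body mass in kg (default 72.4).
#' @param height subject height in m; scales segment lengths linearly
#'   around the 1.80 m default.
#' @return A list of class \code{exo_model_spec}.
#' @export
default_model_spec <- function(mass = 72.4, height = 1.80) {
  hs <- height / 1.80
  ms <- mass / 72.4

  deg <- pi / 180

  # subtalar axis: 42 deg from horizontal, 23 deg medially deviated (right)
  st_ax <- c(cos(42 * deg) * cos(23 * deg), sin(42 * deg),
             -cos(42 * deg) * sin(23 * deg))
  st_ax <- st_ax / sqrt(sum(st_ax^2))
  st_ax_l <- -c(st_ax[1], st_ax[2], -st_ax[3])  # mirrored, +q = inversion

  seg <- list(
    femur_len = 0.47 * hs, tibia_len = 0.46 * hs,
    hip_off = c(0, -0.07, 0.085) * hs,
    lumbar_off = c(-0.03, 0.10, 0) * hs,
    talus_to_subtalar = c(0, -0.04, 0) * hs,
    mtp_off = c(0.165, -0.035, 0) * hs)

  joint <- function(name, type, parent_joint, axis, offset, body = NULL,
                    range = c(-10, 10)) {
    list(name = name, type = type, parent = parent_joint, axis = axis,
         offset = offset, body = body, range = range)
  }
  body <- function(name, mass, com, inertia_diag) {
    list(name = name, mass = mass, com = com, inertia = inertia_diag)
  }
  dummy <- function(name) body(name, 0, c(0, 0, 0), c(0, 0, 0))

  bodies <- list(
    pelvis = body("pelvis", 10.2 * ms, c(0, 0, 0), c(0.08, 0.09, 0.07) * ms * hs^2),
    torso  = body("torso", 37.6 * ms, c(0, 0.25, 0) * hs, c(2.0, 0.9, 1.8) * ms * hs^2),
    femur  = body("femur", 7.5 * ms, c(0, -0.18, 0) * hs, c(0.12, 0.025, 0.12) * ms * hs^2),
    tibia  = body("tibia", 3.5 * ms, c(0, -0.19, 0) * hs, c(0.045, 0.006, 0.045) * ms * hs^2),
    talus  = body("talus", 0.10 * ms, c(0, 0, 0), c(0.001, 0.001, 0.001) * ms * hs^2),
    calcn  = body("calcn", 1.00 * ms, c(0.05, -0.02, 0) * hs, c(0.002, 0.004, 0.004) * ms * hs^2),
    toes   = body("toes", 0.20 * ms, c(0.03, 0, 0) * hs, c(5e-4, 5e-4, 5e-4) * ms * hs^2))

  leg_joints <- function(side) {
    sgn <- if (side == "r") 1 else -1
    sfx <- paste0("_", side)
    hip_off <- seg$hip_off * c(1, 1, sgn)
    add_ax <- c(sgn, 0, 0)
    rot_ax <- c(0, sgn, 0)
    st <- if (side == "r") st_ax else st_ax_l
    list(
      joint(paste0("hip_flexion", sfx), "pin", "pelvis_rotation", c(0, 0, 1),
            hip_off, range = c(-0.70, 2.0)),
      joint(paste0("hip_adduction", sfx), "pin", paste0("hip_flexion", sfx),
            add_ax, c(0, 0, 0), range = c(-0.7, 0.7)),
      joint(paste0("hip_rotation", sfx), "pin", paste0("hip_adduction", sfx),
            rot_ax, c(0, 0, 0), body = paste0("femur", sfx), range = c(-0.7, 0.7)),
      joint(paste0("knee", sfx), "pin", paste0("hip_rotation", sfx), c(0, 0, -1),
            c(0, -seg$femur_len, 0), body = paste0("tibia", sfx),
            range = c(-0.26, 1.9)),
      joint(paste0("ankle", sfx), "pin", paste0("knee", sfx), c(0, 0, 1),
            c(0, -seg$tibia_len, 0), body = paste0("talus", sfx),
            range = c(-0.9, 0.7)),
      joint(paste0("subtalar", sfx), "pin", paste0("ankle", sfx), st,
            seg$talus_to_subtalar, body = paste0("calcn", sfx),
            range = c(-0.6, 0.6)),
      joint(paste0("mtp", sfx), "pin", paste0("subtalar", sfx), c(0, 0, 1),
            seg$mtp_off, body = paste0("toes", sfx), range = c(-0.5, 1.0)))
  }

  joints <- c(list(
    joint("pelvis_tx", "slider", NA, c(1, 0, 0), c(0, 0, 0), range = c(-50, 50)),
    joint("pelvis_ty", "slider", "pelvis_tx", c(0, 1, 0), c(0, 0, 0), range = c(0, 2.5)),
    joint("pelvis_tz", "slider", "pelvis_ty", c(0, 0, 1), c(0, 0, 0), range = c(-5, 5)),
    joint("pelvis_tilt", "pin", "pelvis_tz", c(0, 0, 1), c(0, 0, 0), range = c(-1.0, 1.0)),
    joint("pelvis_list", "pin", "pelvis_tilt", c(1, 0, 0), c(0, 0, 0), range = c(-1.0, 1.0)),
    joint("pelvis_rotation", "pin", "pelvis_list", c(0, 1, 0), c(0, 0, 0),
          body = "pelvis", range = c(-1.0, 1.0)),
    joint("lumbar_extension", "pin", "pelvis_rotation", c(0, 0, 1), seg$lumbar_off,
          range = c(-0.6, 0.6)),
    joint("lumbar_bending", "pin", "lumbar_extension", c(1, 0, 0), c(0, 0, 0),
          range = c(-0.6, 0.6)),
    joint("lumbar_rotation", "pin", "lumbar_bending", c(0, 1, 0), c(0, 0, 0),
          body = "torso", range = c(-0.6, 0.6))),
    leg_joints("r"), leg_joints("l"))

  # contact spheres (calcn frame; origin at the subtalar joint). The medial
  # and lateral metatarsal spheres are 0.11 m apart: the foot width used to
  # normalize COP outcomes.
  sphere_layout <- function(side) {
    sgn <- if (side == "r") 1 else -1
    sfx <- paste0("_", side)
    list(
      list(body = paste0("calcn", sfx), loc = c(-0.04, -0.035, 0) * c(hs, hs, sgn * hs),
           radius = 0.03 * hs, foot = side, group = "heel"),
      list(body = paste0("calcn", sfx), loc = c(0.09, -0.04, 0.045 * sgn) * hs,
           radius = 0.025 * hs, foot = side, group = "mid"),
      list(body = paste0("calcn", sfx), loc = c(0.09, -0.04, -0.045 * sgn) * hs,
           radius = 0.025 * hs, foot = side, group = "mid"),
      list(body = paste0("calcn", sfx), loc = c(0.14, -0.04, 0.055 * sgn) * hs,
           radius = 0.025 * hs, foot = side, group = "met"),
      list(body = paste0("calcn", sfx), loc = c(0.14, -0.04, -0.055 * sgn) * hs,
           radius = 0.025 * hs, foot = side, group = "met"),
      list(body = paste0("toes", sfx), loc = c(0.04, -0.005, 0) * hs,
           radius = 0.025 * hs, foot = side, group = "toe"))
  }
  spheres <- c(sphere_layout("r"), sphere_layout("l"))

  muscles <- default_muscle_table()

  spec <- list(
    name = "reduced_walker",
    total_mass = mass, height = height, gravity = 9.81,
    bodies = bodies, joints = joints, segments = seg,
    spheres = spheres, muscles = muscles,
    passive = default_passive_params(mass),
    contact = default_contact_params())
  class(spec) <- "exo_model_spec"
  spec
}

#' Default passive force-element parameters
#'
#' Mass-scaled lumbar springs, joint dampers, the MTP spring, the diagonal
#' ankle-subtalar bushing and exponential range-of-motion guard parameters.
#' All values in SI units (N m rad^-1, N m s rad^-1).
#'
#' @param mass total body mass kg, used to scale the lumbar springs.
#' @export
default_passive_params <- function(mass = 72.4) {
  list(
    lumbar_k = c(extension = 1.0, bending = 1.5, rotation = 0.5) * mass,
    lumbar_damping = 2.0,
    ankle_damping = 2.0,
    subtalar_damping = 2.0,
    mtp_damping = 2.0,
    mtp_k = 25.0,
    bushing_k = 40.0, bushing_damping = 1.0,
    expo_c1 = 1.0, expo_c2 = 10.0, expo_margin = 5 * pi / 180,
    expo_damping = 0.1)
}

#' Default smoothed Hunt-Crossley contact parameters
#'
#' Plane-strain stiffness in N m^-3/2, dissipation in s m^-1, friction
#' coefficients, transition velocity in m s^-1 and the softplus smoothing
#' sharpness in m^-1 used to keep the normal force C1 across touchdown.
#' @export
default_contact_params <- function() {
  list(stiffness = 1e6, dissipation = 2.0,
       mu_static = 0.8, mu_dynamic = 0.8, mu_viscous = 0.5,
       v_trans = 0.2, smoothing = 1e4)
}

#' Default muscle parameter table (12 muscles per leg)
#'
#' Hill-type muscle parameters with polynomial (here: constant-coefficient)
#' path models; the linear coefficient c1 of each spanned coordinate is the
#' muscle-tendon length derivative, so the moment arm is -c1. Tendon
#' compliance (strain 0.10 at maximum isometric force) is enabled only for
#' soleus and the two gastrocnemius heads; all other tendons are rigid.
#' Activation/deactivation time constants are 0.015 s and 0.060 s.
#'
#' Because the left-leg joint axes are mirrored so that positive coordinates
#' mean the same anatomical motion on both sides, one table serves both legs.
#'
#' @return data frame, one row per muscle template.
#' @export
default_muscle_table <- function() {
  m <- function(name, fiso, lopt, lts, alpha, eps0, coords, c1) {
    list(name = name, fiso = fiso, lopt = lopt, lts = lts, alpha = alpha,
         eps0 = eps0, tact = 0.015, tdeact = 0.060, vmax = 10,
         coords = coords, c1 = c1)
  }
  list(
    m("glut_max", 1900, 0.145, 0.125, 0.20, NA, "hip_flexion", 0.062),
    m("glut_med", 2600, 0.085, 0.065, 0.14, NA, "hip_adduction", 0.055),
    m("iliopsoas", 2000, 0.115, 0.115, 0.14, NA, "hip_flexion", -0.042),
    m("hamstrings", 3000, 0.105, 0.330, 0.20, NA,
      c("hip_flexion", "knee"), c(0.060, -0.030)),
    m("rect_fem", 1200, 0.115, 0.310, 0.12, NA,
      c("hip_flexion", "knee"), c(-0.040, 0.045)),
    m("vasti", 5000, 0.090, 0.220, 0.08, NA, "knee", 0.045),
    m("gas_med", 1600, 0.060, 0.390, 0.30, 0.10,
      c("knee", "ankle", "subtalar"), c(-0.020, 0.048, -0.005)),
    m("gas_lat", 700, 0.064, 0.380, 0.21, 0.10,
      c("knee", "ankle", "subtalar"), c(-0.018, 0.046, -0.003)),
    m("soleus", 3600, 0.050, 0.250, 0.49, 0.10,
      c("ankle", "subtalar"), c(0.048, -0.006)),
    m("tib_ant", 900, 0.098, 0.220, 0.17, NA,
      c("ankle", "subtalar"), c(-0.040, -0.012)),
    m("tib_post", 1600, 0.031, 0.310, 0.25, NA,
      c("ankle", "subtalar"), c(0.012, -0.016)),
    m("per_long", 950, 0.050, 0.345, 0.18, NA,
      c("ankle", "subtalar"), c(0.010, 0.020)))
}
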