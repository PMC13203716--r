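# Simulation configuration -----------------------------------------------
#
# All user-facing angular quantities are in degrees (mirroring the
# published parameter table); internally everything is radians and SI.

#' Build a simulation configuration
#'
#' Assembles and validates the full parameter set of the squat model:
#' anthropometry, reference-motion amplitudes, per-joint constitutive
#' parameters, tracking weights, coordinate bounds, load cases and solver
#' settings.  Defaults reproduce the published parameter table of the
#' model (segment lengths, widths, motion amplitudes, 40 frames,
#' smoothstep profile) plus packaged defaults for the quantities the
#' source model leaves symbolic (joint stiffnesses and capacities,
#' tracking weights, yield ratio).
#'
#' Angles are given in degrees at this boundary and converted to radians
#' internally.  Lengths are metres, moments newton-metres, masses kg.
#'
#' @param L_shank,L_thigh,L_torso Segment lengths (m).
#' @param pelvis_width,shoulder_width Transverse widths (m).
#' @param foot_length,heel_back Foot geometry (m); visualization only.
#' @param leg_clearance Margin (m) by which the initial pelvis height sits
#'   inside the kinematic reachability annulus: `zp0 = L_shank + L_thigh -
#'   leg_clearance` unless `zp0` is given.
#' @param pelvis_drop_max,pelvis_backshift_max Vertical and posterior
#'   pelvis excursions of the reference motion (m).
#' @param torso_pitch_max,pelvis_yaw_max,pelvis_tilt_x_max Rotational
#'   amplitudes of the reference motion (deg).
#' @param footYawL,footYawR Horizontal foot yaw angles (deg) defining the
#'   local sagittal plane of each leg.
#' @param nSteps Number of motion frames (uniform in the normalized motion
#'   parameter `s`, endpoints included).
#' @param profile Reference interpolation profile; only `"smoothstep"`
#'   (`f(s) = 3 s^2 - 2 s^3`) is supported.
#' @param xp0,zp0 Initial pelvis coordinates (m); `NULL` means the
#'   defaults `xp0 = 0`, `zp0 = L_shank + L_thigh - leg_clearance`.
#' @param ankle_L,ankle_R Fixed 3-D ankle positions (m); `NULL` places the
#'   ankles symmetrically about the origin at height 0 with lateral
#'   separation `pelvis_width`.
#' @param joints Named list with elements `ankle`, `knee`, `hip`, `torso`,
#'   each a list with `My` (capacity, N m), `ke` (elastic stiffness,
#'   N m/rad), `kp` (post-yield stiffness, N m/rad) and `eta_y` (yield
#'   ratio in (0,1)).  Partial lists are merged over the defaults:
#'   capacities 150/250/300/250 N m for ankle/knee/hip/torso,
#'   `ke = 20 My` per radian, `kp = 0.075 ke`, `eta_y = 0.95`.
#' @param tracking_weights Named numeric for (`xp`, `zp`, `psi_p`,
#'   `phi_p`, `theta_t`): translations N/m, rotations N m/rad.
#' @param bounds List with `translation_margin` (m, box half-width around
#'   the per-frame reference translations) and `rotation_limit_deg`
#'   (absolute bound on each rotational coordinate).
#' @param solver List with `rel_tol` (relative objective-change
#'   convergence tolerance), `max_iter`, `feasibility_margin` (m, margin
#'   `eps` on the reachability inequalities) and `ik_tol` (m, tolerance of
#'   the pure inverse-kinematics reachability check).
#' @param gravity Gravitational acceleration (m/s^2).
#' @param masses Default barbell masses (kg) for [sweep_loads()].
#'
#' @return An object of class `squat_config`: a named list with elements
#'   `anthro`, `motion`, `joints` (the seven-joint expansion, ordered
#'   ankle_L, knee_L, hip_L, ankle_R, knee_R, hip_R, torso), `weights`,
#'   `bounds`, `solver`, `gravity` and `masses`.  Angles are stored in
#'   radians.
#' @examples
#' cfg <- squat_config()
#' cfg$motion$n_steps
#' symmetric <- squat_config(pelvis_yaw_max = 0, pelvis_tilt_x_max = 0)
#' @export
squat_config <- function(L_shank = 0.45,
                         L_thigh = 0.45,
                         L_torso = 0.60,
                         pelvis_width = 0.28,
                         shoulder_width = 0.38,
                         foot_length = 0.24,
                         heel_back = 0.04,
                         leg_clearance = 0.02,
                         pelvis_drop_max = 0.60,
                         pelvis_backshift_max = 0.18,
                         torso_pitch_max = 30.0,
                         pelvis_yaw_max = 10.0,
                         pelvis_tilt_x_max = 10.0,
                         footYawL = 15.0,
                         footYawR = -15.0,
                         nSteps = 40L,
                         profile = "smoothstep",
                         xp0 = NULL,
                         zp0 = NULL,
                         ankle_L = NULL,
                         ankle_R = NULL,
                         joints = list(),
                         tracking_weights = c(xp = 2e4, zp = 2e4,
                                              psi_p = 500, phi_p = 500,
                                              theta_t = 500),
                         bounds = list(translation_margin = 0.5,
                                       rotation_limit_deg = 90),
                         solver = list(rel_tol = 1e-10,
                                       max_iter = 200L,
                                       feasibility_margin = 1e-6,
                                       ik_tol = 1e-9),
                         gravity = 9.81,
                         masses = c(0, 60, 100, 140)) {
  stopifnot(identical(profile, "smoothstep"))
  lengths <- c(L_shank = L_shank, L_thigh = L_thigh, L_torso = L_torso,
               pelvis_width = pelvis_width, shoulder_width = shoulder_width,
               foot_length = foot_length)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all segment lengths and widths must be finite and positive", call. = FALSE)
  if (abs(footYawL) >= 90 || abs(footYawR) >= 90)
    stop("foot yaw angles must satisfy |alpha| < 90 deg", call. = FALSE)

  if (is.null(xp0)) xp0 <- 0
  if (is.null(zp0)) zp0 <- L_shank + L_thigh - leg_clearance
  if (zp0 <= 0) stop("initial pelvis height zp0 must be positive", call. = FALSE)
  if (is.null(ankle_L)) ankle_L <- c(0,  pelvis_width / 2, 0)
  if (is.null(ankle_R)) ankle_R <- c(0, -pelvis_width / 2, 0)
  ankle_L <- as.numeric(ankle_L); ankle_R <- as.numeric(ankle_R)
  if (length(ankle_L) != 3L || length(ankle_R) != 3L)
    stop("ankle positions must be 3-vectors", call. = FALSE)
  if (all(ankle_L == ankle_R))
    stop("left and right ankle positions must differ", call. = FALSE)

  anthro <- list(
    L_shank = L_shank, L_thigh = L_thigh, L_torso = L_torso,
    pelvis_width = pelvis_width, shoulder_width = shoulder_width,
    foot_length = foot_length, heel_back = heel_back,
    leg_clearance = leg_clearance,
    foot_yaw_L = deg2rad(footYawL), foot_yaw_R = deg2rad(footYawR),
    ankle_L = ankle_L, ankle_R = ankle_R)

  nSteps <- as.integer(nSteps)
  if (is.na(nSteps) || nSteps < 2L)
    stop("nSteps must be an integer >= 2", call. = FALSE)
  if (pelvis_drop_max <= 0)
    stop("pelvis_drop_max must be positive", call. = FALSE)
  motion <- list(
    xp0 = xp0, zp0 = zp0,
    drop = pelvis_drop_max, backshift = pelvis_backshift_max,
    yaw_max = deg2rad(pelvis_yaw_max),
    obliquity_max = deg2rad(pelvis_tilt_x_max),
    pitch_max = deg2rad(torso_pitch_max),
    n_steps = nSteps, profile = profile)

  joints <- resolve_joint_params(joints)

  tracking_weights <- tracking_weights[COORD_NAMES]
  if (anyNA(tracking_weights) || any(tracking_weights < 0) ||
      all(tracking_weights == 0))
    stop("tracking_weights must be named for ", paste(COORD_NAMES, collapse = ", "),
         ", non-negative, with at least one positive entry", call. = FALSE)

  bounds <- modifyList(list(translation_margin = 0.5, rotation_limit_deg = 90),
                       bounds)
  solver <- modifyList(list(rel_tol = 1e-10, max_iter = 200L,
                            feasibility_margin = 1e-6, ik_tol = 1e-9),
                       solver)
  if (gravity <= 0) stop("gravity must be positive", call. = FALSE)
  if (any(masses < 0)) stop("barbell masses must be non-negative", call. = FALSE)

  structure(list(anthro = anthro, motion = motion, joints = joints,
                 weights = tracking_weights, bounds = bounds,
                 solver = solver, gravity = gravity, masses = masses),
            class = "squat_config")
}

# default per-group constitutive parameters; the published model leaves these
# symbolic ("indicative rather than subject-specific"), so the package ships a
# calibration documented in the methods vignette.
default_joint_groups <- function() {
  cap <- c(ankle = 150, knee = 250, hip = 300, torso = 250)
  lapply(cap, function(My)
    list(My = My, ke = 20 * My, kp = 0.075 * 20 * My, eta_y = 0.95))
}

# merge user overrides (keyed by group ankle/knee/hip/torso) over defaults and
# expand to the seven modeled joints
resolve_joint_params <- function(joints) {
  groups <- default_joint_groups()
  if (length(joints)) {
    bad <- setdiff(names(joints), names(groups))
    if (length(bad))
      stop("unknown joint group(s): ", paste(bad, collapse = ", "),
           " (expected ankle, knee, hip, torso)", call. = FALSE)
    for (g in names(joints)) {
      extra <- setdiff(names(joints[[g]]), c("My", "ke", "kp", "eta_y"))
      if (length(extra))
        stop("unknown joint parameter(s) for ", g, ": ",
             paste(extra, collapse = ", "), call. = FALSE)
      groups[[g]] <- modifyList(groups[[g]], joints[[g]])
    }
  }
  for (g in names(groups)) {
    p <- groups[[g]]
    if (!(p$ke > p$kp && p$kp > 0))
      stop("joint ", g, ": need ke > kp > 0", call. = FALSE)
    if (p$My <= 0) stop("joint ", g, ": capacity My must be positive", call. = FALSE)
    if (p$eta_y <= 0 || p$eta_y >= 1)
      stop("joint ", g, ": yield ratio eta_y must lie in (0,1)", call. = FALSE)
  }
  group_of <- c(ankle_L = "ankle", knee_L = "knee", hip_L = "hip",
                ankle_R = "ankle", knee_R = "knee", hip_R = "hip",
                torso = "torso")
  setNames(lapply(JOINT_NAMES, function(j) groups[[group_of[[j]]]]),
           JOINT_NAMES)
}

#' @export
print.squat_config <- function(x, ...) {
  m <- x$motion
  cat("<squat_config>\n")
  cat(sprintf("  segments: shank %.2f m, thigh %.2f m, torso %.2f m\n",
              x$anthro$L_shank, x$anthro$L_thigh, x$anthro$L_torso))
  cat(sprintf("  reference: drop %.2f m, backshift %.2f m, pitch %.1f deg, %d frames\n",
              m$drop, m$backshift, rad2deg(m$pitch_max), m$n_steps))
  cat(sprintf("  yaw/obliquity amplitudes: %.1f / %.1f deg\n",
              rad2deg(m$yaw_max), rad2deg(m$obliquity_max)))
  caps <- vapply(x$joints, `[[`, numeric(1), "My")
  cat("  joint capacities (N m): ",
      paste(sprintf("%s=%g", names(caps), caps), collapse = ", "), "\n", sep = "")
  cat(sprintf("  load cases: %s kg, g = %.2f m/s^2\n",
              paste(x$masses, collapse = ", "), x$gravity))
  invisible(x)
}

# keys accepted in a JSON configuration file (published parameter-table names
# verbatim, plus namespaced extensions); anything else is a typo error
CONFIG_KEYS <- c("L_shank", "L_thigh", "L_torso", "pelvis_width",
                 "shoulder_width", "foot_length", "heel_back",
                 "leg_clearance", "pelvis_drop_max", "pelvis_backshift_max",
                 "torso_pitch_max", "pelvis_yaw_max", "pelvis_tilt_x_max",
                 "footYawL", "footYawR", "nSteps", "profile",
                 "xp0", "zp0", "ankle_L", "ankle_R",
                 "joints", "tracking_weights", "bounds", "solver",
                 "gravity", "masses")

#' Read a configuration file
#'
#' Reads a JSON configuration whose top-level keys use the published
#' parameter-table names verbatim (`L_shank`, `pelvis_width`, `nSteps`,
#' ...) plus the namespaced keys `joints`, `tracking_weights`, `bounds`,
#' `solver`, `gravity`, `masses`, `xp0`, `zp0`, `ankle_L`, `ankle_R`.
#' Unknown keys are errors.  Missing keys fall back to the packaged
#' defaults of [squat_config()].
#'
#' @param path Path to a JSON file, or `NULL` for the packaged default
#'   configuration.
#' @return A [squat_config()] object.
#' @seealso [default_config_path()] for the packaged file.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) path <- default_config_path()
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  config_from_list(raw, context = path)
}

# build a squat_config from a plain named list (file or manifest contents)
config_from_list <- function(raw, context = "config") {
  if (!is.list(raw) || is.null(names(raw)))
    stop(context, ": expected a JSON object of named parameters", call. = FALSE)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown))
    stop(context, ": unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(raw$tracking_weights))
    raw$tracking_weights <- unlist(raw$tracking_weights)
  do.call(squat_config, raw)
}

#' Path of the packaged default configuration
#'
#' The packaged file reproduces the published parameter table exactly; a
#' `symmetric` variant zeroes the pelvis yaw and obliquity amplitudes for
#' strictly sagittal-symmetric motion.
#'
#' @param preset `"default"` or `"symmetric"`.
#' @return File path of the packaged JSON configuration.
#' @export
default_config_path <- function(preset = c("default", "symmetric")) {
  preset <- match.arg(preset)
  fn <- if (preset == "default") "default_config.json" else "symmetric_config.json"
  system.file("extdata", fn, package = "squatsim", mustWork = TRUE)
}

# serializable user-facing representation (degrees / published key names)
config_as_keyvalue <- function(config) {
  a <- config$anthro; m <- config$motion
  list(
    L_shank = a$L_shank, L_thigh = a$L_thigh, L_torso = a$L_torso,
    pelvis_width = a$pelvis_width, shoulder_width = a$shoulder_width,
    foot_length = a$foot_length, heel_back = a$heel_back,
    leg_clearance = a$leg_clearance,
    pelvis_drop_max = m$drop, pelvis_backshift_max = m$backshift,
    torso_pitch_max = rad2deg(m$pitch_max),
    pelvis_yaw_max = rad2deg(m$yaw_max),
    pelvis_tilt_x_max = rad2deg(m$obliquity_max),
    footYawL = rad2deg(a$foot_yaw_L), footYawR = rad2deg(a$foot_yaw_R),
    nSteps = m$n_steps, profile = m$profile,
    xp0 = m$xp0, zp0 = m$zp0,
    ankle_L = a$ankle_L, ankle_R = a$ankle_R,
    joints = setNames(
      lapply(c("ankle_L", "knee_L", "hip_L", "torso"), function(j)
        config$joints[[j]][c("My", "ke", "kp", "eta_y")]),
      c("ankle", "knee", "hip", "torso")),
    tracking_weights = as.list(config$weights),
    bounds = config$bounds,
    solver = config$solver,
    gravity = config$gravity,
    masses = config$masses)
}
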