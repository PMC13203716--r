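# Load-independent reference squat trajectory -----------------------------

#' Smoothstep interpolation profile
#'
#' `f(s) = 3 s^2 - 2 s^3` on `[0, 1]`: endpoints 0 and 1 with zero slope
#' at both, so the discretized motion has no velocity discontinuities at
#' the top or bottom of the squat.
#'
#' @param s Normalized motion parameter(s) in `[0, 1]` (0 = upright,
#'   1 = deepest position).
#' @return `f(s)`, same length as `s`.
#' @export
smoothstep <- function(s) {
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop("smoothstep is defined on s in [0, 1]", call. = FALSE)
  3 * s^2 - 2 * s^3
}

#' Reference generalized coordinates at a motion parameter
#'
#' The pelvis descends by `drop * f(s)` and shifts posteriorly by
#' `backshift * f(s)` from its initial position, while pelvis yaw, pelvic
#' obliquity and torso pitch ramp to their maxima with the same profile.
#'
#' @param s Normalized motion parameter in `[0, 1]`.
#' @param motion Motion-amplitude list (the `motion` element of a
#'   [squat_config()]).
#' @return Named numeric length-5 generalized-coordinate vector (m / rad).
#' @export
reference_coords <- function(s, motion) {
  f <- smoothstep(s)
  setNames(c(motion$xp0 - motion$backshift * f,
             motion$zp0 - motion$drop * f,
             motion$yaw_max * f,
             motion$obliquity_max * f,
             motion$pitch_max * f),
           COORD_NAMES)
}

#' Build the reference squat trajectory
#'
#' Samples the normalized motion parameter uniformly on `[0, 1]`
#' (`n_steps` frames, endpoints included), evaluates the reference
#' generalized coordinates at each frame and derives the reference joint
#' angles from the reference geometry via [forward_pose()] and
#' [extract_joint_angles()].  Because the reference angles are derived
#' (not independently prescribed), the joint deviations are exactly zero
#' along the reference motion.
#'
#' @param config A [squat_config()].
#' @return A tibble of class `squat_reference`, one row per frame, with
#'   columns `frame`, `s`, the five generalized coordinates and the seven
#'   reference joint angles (`theta_<joint>`, rad).
#' @examples
#' ref <- build_reference(squat_config(nSteps = 5))
#' ref$zp
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "squat_config"))
  motion <- config$motion
  s <- seq(0, 1, length.out = motion$n_steps)
  rows <- purrr::map(seq_along(s), function(i) {
    q <- reference_coords(s[i], motion)
    pose <- tryCatch(
      forward_pose(q, config$anthro, ik_tol = config$solver$ik_tol),
      error = function(e)
        stop(sprintf("reference frame %d (s = %.3f) is not reachable: %s",
                     i, s[i], conditionMessage(e)), call. = FALSE))
    theta <- extract_joint_angles(pose, q, config$anthro)
    tibble::tibble(frame = i, s = s[i], !!!as.list(q),
                   !!!setNames(as.list(as.numeric(theta)),
                               paste0("theta_", JOINT_NAMES)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("squat_reference", class(out))
  out
}
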