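# Forward geometry and per-leg planar inverse kinematics ------------------
#
# Global frame: X anterior-posterior, Y left-right, Z vertical.  Posture is
# described by five generalized coordinates q = (xp, zp, psi_p, phi_p,
# theta_t): pelvis translation in the sagittal plane, pelvis yaw about Z,
# pelvic obliquity about X, torso pitch about Y.  Ankles are fixed in space;
# each leg is solved in its own vertical plane defined by the foot yaw.

#' Elementary rotation matrices
#'
#' Right-handed rotations about the global Z and X axes.  The pelvis
#' orientation is their composition `Rp = rotation_z(psi) %*% rotation_x(phi)`.
#'
#' @param psi,phi Rotation angle (rad).
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @examples
#' rotation_z(pi / 2) %*% c(1, 0, 0) # ~ (0, 1, 0)
#' @export
rotation_z <- function(psi) {
  stopifnot(is.finite(psi))
  c_ <- cos(psi); s_ <- sin(psi)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), nrow = 3)
}

#' @rdname rotation_z
#' @export
rotation_x <- function(phi) {
  stopifnot(is.finite(phi))
  c_ <- cos(phi); s_ <- sin(phi)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), nrow = 3)
}

# validate / name a generalized-coordinate vector
as_coords <- function(q) {
  q <- as.numeric(q)
  if (length(q) != 5L || any(!is.finite(q)))
    stop("generalized coordinates must be 5 finite numbers (",
         paste(COORD_NAMES, collapse = ", "), ")", call. = FALSE)
  setNames(q, COORD_NAMES)
}

#' Pelvis frame and hip joint centers
#'
#' Places the pelvis center at `(xp, 0, zp)` (lateral pelvis translation is
#' neglected), orients it by yaw then obliquity, and offsets the hip joint
#' centers by half the pelvis width along the local transverse axis
#' `ey_p = Rp (0,1,0)`.
#'
#' @param q Generalized coordinates (length-5 numeric; see [squat_config()]).
#' @param anthro Anthropometry list (the `anthro` element of a config).
#' @return List with `pp` (pelvis center), `Rp` (3x3 rotation), `hip_L`,
#'   `hip_R` (3-vectors, m).
#' @export
pelvis_frame <- function(q, anthro) {
  q <- as_coords(q)
  Rp <- rotation_z(q[["psi_p"]]) %*% rotation_x(q[["phi_p"]])
  pp <- c(q[["xp"]], 0, q[["zp"]])
  ey <- Rp %*% c(0, 1, 0)
  half <- anthro$pelvis_width / 2
  list(pp = pp, Rp = Rp,
       hip_L = pp + half * as.numeric(ey),
       hip_R = pp - half * as.numeric(ey))
}

#' Project a hip center into a leg's local sagittal plane
#'
#' Each leg is solved in the vertical plane through its ankle whose local
#' anterior axis is the foot direction `(cos a, sin a, 0)`; the local
#' vertical is the global Z.
#'
#' @param hip,ankle 3-vectors (m).
#' @param alpha Foot yaw angle (rad).
#' @return Numeric `c(xH, zH)`: planar hip coordinates relative to the ankle.
#' @export
project_hip_to_leg_plane <- function(hip, ankle, alpha) {
  d <- unname(hip - ankle)
  c(xH = d[1] * cos(alpha) + d[2] * sin(alpha), zH = d[3])
}

#' Kinematic reachability of a hip position
#'
#' A planar hip position admits a knee solution iff its distance to the
#' ankle lies in the annulus `[|Ls - Lf|, Ls + Lf]` (up to `tol`).
#'
#' @param xH,zH Planar hip coordinates (m).
#' @param Ls,Lf Shank and thigh lengths (m).
#' @param tol Tolerance (m) on both annulus boundaries.
#' @return Logical flag.
#' @export
is_reachable <- function(xH, zH, Ls, Lf, tol = 1e-9) {
  stopifnot(Ls > 0, Lf > 0)
  d <- sqrt(xH^2 + zH^2)
  d >= abs(Ls - Lf) - tol & d <= Ls + Lf + tol
}

#' Planar knee position by circle intersection
#'
#' The knee lies on the circle of radius `Ls` about the ankle (local
#' origin) and the circle of radius `Lf` about the hip.  Of the up-to-two
#' intersections, the anterior branch (larger local x) is returned,
#' matching squat physiology where the knees travel forward; at the
#' tangent configuration both branches coincide.
#'
#' @inheritParams is_reachable
#' @return Numeric `c(xK, zK)` (m).
#' @export
solve_knee <- function(xH, zH, Ls, Lf, tol = 1e-9) {
  xH <- unname(xH); zH <- unname(zH)
  d2 <- xH^2 + zH^2
  d <- sqrt(d2)
  if (!is_reachable(xH, zH, Ls, Lf, tol))
    stop(sprintf(paste0("unreachable configuration: hip-ankle distance %.6f m ",
                        "outside [%.6f, %.6f]"),
                 d, abs(Ls - Lf), Ls + Lf), call. = FALSE)
  if (d < 1e-12) {
    # degenerate concentric case (only reachable when Ls == Lf): every point
    # of the shank circle solves both equations; take the anterior one
    return(c(xK = Ls, zK = 0))
  }
  a <- (d2 + Ls^2 - Lf^2) / (2 * d)
  h2 <- Ls^2 - a^2
  h <- sqrt(max(h2, 0))            # clamp tangent-case roundoff
  ux <- xH / d; uz <- zH / d
  # two candidates: base point +/- h along the in-plane perpendicular
  x1 <- a * ux + h * uz; z1 <- a * uz - h * ux
  x2 <- a * ux - h * uz; z2 <- a * uz + h * ux
  if (x1 >= x2) c(xK = x1, zK = z1) else c(xK = x2, zK = z2)
}

#' Forward body pose from generalized coordinates
#'
#' Composes the pelvis frame, the per-leg planar inverse kinematics and
#' the torso/shoulder construction into the full set of 3-D joint
#' positions.  The torso is a rigid segment of length `L_torso` along
#' `dt = (sin(theta_t) cos(psi_p), sin(theta_t) sin(psi_p), cos(theta_t))`;
#' the shoulder transverse direction follows the pelvis yaw.
#'
#' @inheritParams pelvis_frame
#' @param ik_tol Reachability tolerance (m) passed to [solve_knee()].
#' @return Object of class `body_pose`: list with `pp`, `Rp`, `hip_L`,
#'   `hip_R`, `knee_L`, `knee_R`, `ankle_L`, `ankle_R`, `shoulder_center`,
#'   `shoulder_L`, `shoulder_R` (3-vectors, m), `torso_dir` (unit
#'   3-vector), and `leg_local` (per-side planar hip/knee coordinates).
#' @export
forward_pose <- function(q, anthro, ik_tol = 1e-9) {
  q <- as_coords(q)
  pf <- pelvis_frame(q, anthro)
  Ls <- anthro$L_shank; Lf <- anthro$L_thigh

  solve_side <- function(hip, ankle, alpha, side) {
    loc <- project_hip_to_leg_plane(hip, ankle, alpha)
    if (!is_reachable(loc[["xH"]], loc[["zH"]], Ls, Lf, ik_tol))
      stop(sprintf(paste0("unreachable configuration on the %s leg: planar ",
                          "hip-ankle distance %.6f m outside [%.6f, %.6f]"),
                   side, sqrt(sum(loc^2)), abs(Ls - Lf), Ls + Lf),
           call. = FALSE)
    knee_loc <- solve_knee(loc[["xH"]], loc[["zH"]], Ls, Lf, ik_tol)
    ex <- c(cos(alpha), sin(alpha), 0)
    list(local = c(loc, knee_loc),
         knee = ankle + knee_loc[["xK"]] * ex + knee_loc[["zK"]] * c(0, 0, 1))
  }

  left  <- solve_side(pf$hip_L, anthro$ankle_L, anthro$foot_yaw_L, "left")
  right <- solve_side(pf$hip_R, anthro$ankle_R, anthro$foot_yaw_R, "right")

  st <- sin(q[["theta_t"]]); ct <- cos(q[["theta_t"]])
  dt <- c(st * cos(q[["psi_p"]]), st * sin(q[["psi_p"]]), ct)
  sc <- pf$pp + anthro$L_torso * dt
  ey_s <- as.numeric(rotation_z(q[["psi_p"]]) %*% c(0, 1, 0))
  half_s <- anthro$shoulder_width / 2

  structure(list(
    q = q, pp = pf$pp, Rp = pf$Rp,
    hip_L = pf$hip_L, hip_R = pf$hip_R,
    knee_L = left$knee, knee_R = right$knee,
    ankle_L = anthro$ankle_L, ankle_R = anthro$ankle_R,
    shoulder_center = sc, torso_dir = dt,
    shoulder_L = sc + half_s * ey_s, shoulder_R = sc - half_s * ey_s,
    leg_local = list(L = left$local, R = right$local)),
    class = "body_pose")
}

# planar segment angle measured from the local vertical, positive when the
# distal-to-proximal direction tilts toward local +x (upright pose => 0)
segment_angle <- function(dx, dz) atan2(dx, dz)

#' Joint angular measures of a pose
#'
#' Extracts the seven scalar joint measures driving the constitutive
#' model.  In each local leg plane the shank angle `theta_s` (ankle to
#' knee) and thigh angle `theta_f` (knee to hip) are measured from the
#' local vertical, positive toward local anterior; then per side
#' `ankle = theta_s`, `knee = theta_s - theta_f`,
#' `hip = theta_f - phi_p`, and the torso measure is
#' `theta_t - phi_p` (torso pitch relative to the pelvis tilt).  Note the
#' pelvic obliquity enters every composite measure with the same sign on
#' both sides, as the model defines it; under load this lets the
#' optimizer relieve sagittal joint deviations through a small pelvic
#' roll, so mirror-symmetric inputs do not guarantee mirror-symmetric
#' corrected postures (see the methods vignette).
#'
#' @param pose A [forward_pose()] result.
#' @param q Generalized coordinates at which `pose` was evaluated.
#' @param anthro Anthropometry list (unused dimensions kept for interface
#'   symmetry).
#' @return Named numeric of length 7 (rad), ordered `ankle_L, knee_L,
#'   hip_L, ankle_R, knee_R, hip_R, torso`, with the auxiliary shank and
#'   thigh angles attached as attribute `"segment_angles"`.
#' @export
extract_joint_angles <- function(pose, q, anthro) {
  q <- as_coords(q)
  side_angles <- function(loc) {
    th_s <- segment_angle(loc[["xK"]], loc[["zK"]])
    th_f <- segment_angle(loc[["xH"]] - loc[["xK"]], loc[["zH"]] - loc[["zK"]])
    c(shank = th_s, thigh = th_f)
  }
  sl <- side_angles(pose$leg_local$L)
  sr <- side_angles(pose$leg_local$R)
  phi <- q[["phi_p"]]
  out <- c(
    ankle_L = sl[["shank"]],
    knee_L  = sl[["shank"]] - sl[["thigh"]],
    hip_L   = sl[["thigh"]] - phi,
    ankle_R = sr[["shank"]],
    knee_R  = sr[["shank"]] - sr[["thigh"]],
    hip_R   = sr[["thigh"]] - phi,
    torso   = q[["theta_t"]] - phi)
  attr(out, "segment_angles") <- c(shank_L = sl[["shank"]], thigh_L = sl[["thigh"]],
                                   shank_R = sr[["shank"]], thigh_R = sr[["thigh"]])
  out
}
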