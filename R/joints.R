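# Bounded tanh moment-rotation joint law, yield and degradation -----------
#
# Each of the seven rotational components (L/R ankle, knee, hip; torso) is a
# nonlinear elastic element: the restoring moment for a deviation dtheta from
# the reference joint angle is
#
#     M(dtheta) = My * tanh(k * dtheta / My)
#
# which is linear (slope k) for small deviations and saturates strictly below
# the capacity My.  Once |M| reaches eta_y * My at a converged frame, the
# joint is declared yielded and its stiffness drops permanently from the
# elastic value ke to the post-yield value kp.

#' Joint restoring moment
#'
#' Saturating moment-rotation law `M = My tanh(k dtheta / My)`: odd in
#' `dtheta`, slope `k` at the origin, `|M| < My` for all finite `dtheta`.
#'
#' @param delta_theta Deviation from the reference joint angle (rad);
#'   vectorized.
#' @param k Active rotational stiffness (N m/rad), positive.
#' @param My Moment capacity (N m), positive.
#' @return Moment (N m).
#' @examples
#' joint_moment(0.25, k = 200, My = 100) # 100 * tanh(0.5)
#' @export
joint_moment <- function(delta_theta, k, My) {
  stopifnot(k > 0, My > 0)
  My * tanh(k * delta_theta / My)
}

#' Joint strain energy
#'
#' Potential of [joint_moment()]:
#' `Pi = (My^2 / k) log(cosh(k dtheta / My))`, non-negative, zero only at
#' zero deviation, with derivative equal to the moment.
#'
#' @inheritParams joint_moment
#' @return Energy (N m).
#' @export
joint_energy <- function(delta_theta, k, My) {
  stopifnot(k > 0, My > 0)
  x <- k * delta_theta / My
  # log(cosh(x)) = |x| + log1p(exp(-2|x|)) - log(2), overflow-safe
  (My^2 / k) * (abs(x) + log1p(exp(-2 * abs(x))) - log(2))
}

#' Total joint energy over the seven modeled joints
#'
#' @param delta_theta Named or ordered numeric of length 7 (rad), joint
#'   order `ankle_L, knee_L, hip_L, ankle_R, knee_R, hip_R, torso`.
#' @param states Joint-state tibble from [joint_states_init()] (supplies
#'   each joint's *active* stiffness).
#' @return Summed energy (N m).
#' @export
total_joint_energy <- function(delta_theta, states) {
  stopifnot(length(delta_theta) == 7L)
  e <- joint_energy(as.numeric(delta_theta), states$k, states$My)
  # pairwise left/right summation keeps the total bitwise invariant under a
  # left-right swap, so mirror-symmetric configurations stay exactly symmetric
  ((e[1] + e[4]) + (e[2] + e[5])) + ((e[3] + e[6]) + e[7])
}

#' Joint utilization measures
#'
#' Two complementary demand-to-capacity ratios: the *demand* utilization
#' `k |dtheta| / My` is the linearized demand and may exceed unity
#' (signalling yielding); the *bounded* utilization `|M| / My =
#' |tanh(k dtheta / My)|` is strictly below one by construction of the
#' saturating law.
#'
#' @inheritParams joint_moment
#' @return List with numeric `demand` and `bounded`.
#' @examples
#' utilization(0.6, k = 200, My = 100) # demand 1.2, bounded tanh(1.2)
#' @export
utilization <- function(delta_theta, k, My) {
  stopifnot(My > 0)
  x <- k * abs(delta_theta) / My
  list(demand = x, bounded = tanh(x))
}

#' Initial joint states
#'
#' @param config A [squat_config()].
#' @return Tibble with one row per joint: `joint`, capacity `My`, elastic
#'   and post-yield stiffnesses `ke`, `kp`, yield ratio `eta_y`, active
#'   stiffness `k` (= `ke` initially), `yielded` flag and `yield_frame`.
#' @export
joint_states_init <- function(config) {
  p <- config$joints
  field <- function(nm) unname(vapply(p, `[[`, numeric(1), nm))
  tibble::tibble(
    joint = JOINT_NAMES,
    My = field("My"), ke = field("ke"), kp = field("kp"),
    eta_y = field("eta_y"),
    k = field("ke"),
    yielded = FALSE,
    yield_frame = NA_integer_)
}

#' Yield check for one joint at a converged frame
#'
#' If the evaluated moment satisfies `|M| >= eta_y * My` and the joint has
#' not yielded yet, the joint is marked yielded and its active stiffness
#' drops permanently to the post-yield value; otherwise the state is
#' returned unchanged.  Yield never reverts.
#'
#' @param moment Converged-frame joint moment (N m).
#' @param state One row of a [joint_states_init()] tibble (or an
#'   equivalent list with `k`, `kp`, `My`, `eta_y`, `yielded`,
#'   `yield_frame`).
#' @param frame Frame index recorded on a new yield event.
#' @return The updated state (same shape as `state`).
#' @export
check_and_apply_yield <- function(moment, state, frame = NA_integer_) {
  if (!state$yielded && abs(moment) >= state$eta_y * state$My) {
    state$yielded <- TRUE
    state$k <- state$kp
    state$yield_frame <- as.integer(frame)
  }
  state
}

# vectorized frame-level update over the 7-joint state tibble
apply_yield_frame <- function(states, moments, frame) {
  new <- !states$yielded & abs(moments) >= states$eta_y * states$My
  states$yielded[new] <- TRUE
  states$k[new] <- states$kp[new]
  states$yield_frame[new] <- as.integer(frame)
  states
}
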