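# Frame-by-frame corrected simulation and load sweeps ----------------------

#' Run a corrected squat simulation for one barbell mass
#'
#' Builds the load-independent reference trajectory, then walks it frame
#' by frame: each frame's posture is the constrained minimizer of the
#' tracking + joint-energy + gravitational objective, warm-started from
#' the previous frame's solution (frame 1 starts from its own reference).
#' After a frame converges, the seven joint moments are evaluated from
#' the saturating moment law and the yield criterion is checked; a newly
#' yielded joint has its stiffness permanently reduced from the next
#' frame onward.  The pipeline contains no randomness: identical inputs
#' give bit-identical results.
#'
#' @param config A [squat_config()].
#' @param mass Barbell mass (kg); weight `mass * gravity` acts vertically
#'   through the shoulders.
#' @return Object of class `squat_sim`: list with
#'   \describe{
#'     \item{frames}{tibble, one row per frame: `s`, reference coordinates
#'       (`*_ref`), corrected coordinates, shoulder-center position,
#'       per-joint deviations `delta_*` (rad), moments `moment_*` (N m),
#'       utilizations `demand_*` / `bounded_*`, objective breakdown and
#'       convergence info.}
#'     \item{summary}{one-row tibble: `mass`, `max_backshift` and
#'       `max_drop` (m, measured from the initial pelvis position),
#'       `max_pitch_deg`, peak absolute moment per joint group (N m),
#'       `max_demand_util`, `max_bounded_util`, `n_yield`.}
#'     \item{yield_log}{tibble of yield events (`joint`, `frame`, `s`,
#'       `moment`, stiffness before/after).}
#'     \item{reference, config, mass}{inputs for reproducibility.}
#'   }
#' @examples
#' \donttest{
#' sim <- run_simulation(squat_config(nSteps = 10), mass = 60)
#' glance(sim)
#' }
#' @export
run_simulation <- function(config, mass = 0) {
  stopifnot(inherits(config, "squat_config"), is.numeric(mass), mass >= 0)
  ref <- build_reference(config)
  n <- nrow(ref)
  Wb <- mass * config$gravity
  states <- joint_states_init(config)
  theta_cols <- paste0("theta_", JOINT_NAMES)

  q_prev <- as_coords(as.numeric(ref[1, COORD_NAMES]))
  rows <- vector("list", n)
  yield_events <- list()

  for (i in seq_len(n)) {
    q_ref <- as_coords(as.numeric(ref[i, COORD_NAMES]))
    theta_ref <- as.numeric(ref[i, theta_cols])
    ctx <- frame_context(q_ref, theta_ref, states, config, Wb)
    sol <- minimize_frame(q_ref, q_prev, ctx)
    if (!sol$report$converged)
      warning(sprintf("frame %d (mass %g kg): solver stopped without meeting the %s tolerance (%s); best iterate kept",
                      i, mass, format(config$solver$rel_tol), sol$report$message),
              call. = FALSE)

    pose <- forward_pose(sol$q, config$anthro, ik_tol = ctx$ik_tol)
    theta <- as.numeric(extract_joint_angles(pose, sol$q, config$anthro))
    dtheta <- theta - theta_ref
    moments <- joint_moment(dtheta, states$k, states$My)
    demand <- states$k * abs(dtheta) / states$My
    bounded <- abs(moments) / states$My

    new_states <- apply_yield_frame(states, moments, i)
    newly <- which(new_states$yielded & !states$yielded)
    if (length(newly))
      yield_events[[length(yield_events) + 1L]] <- tibble::tibble(
        joint = states$joint[newly], frame = i, s = ref$s[i],
        moment = moments[newly],
        k_before = states$k[newly], k_after = new_states$k[newly])

    rows[[i]] <- tibble::tibble(
      frame = i, s = ref$s[i],
      !!!setNames(as.list(as.numeric(q_ref)), paste0(COORD_NAMES, "_ref")),
      !!!setNames(as.list(as.numeric(sol$q)), COORD_NAMES),
      shoulder_x = pose$shoulder_center[1],
      shoulder_z = pose$shoulder_center[3],
      !!!setNames(as.list(dtheta), paste0("delta_", JOINT_NAMES)),
      !!!setNames(as.list(moments), paste0("moment_", JOINT_NAMES)),
      !!!setNames(as.list(demand), paste0("demand_", JOINT_NAMES)),
      !!!setNames(as.list(bounded), paste0("bounded_", JOINT_NAMES)),
      obj_tracking = sol$objective$tracking,
      obj_joint = sol$objective$joint,
      obj_external = sol$objective$external,
      obj_total = sol$objective$total,
      converged = sol$report$converged,
      iterations = sol$report$iterations,
      n_yield_events = length(newly))

    states <- new_states       # degraded stiffness acts from frame i+1
    q_prev <- sol$q
  }

  frames <- dplyr::bind_rows(rows)
  yield_log <- if (length(yield_events)) dplyr::bind_rows(yield_events) else
    tibble::tibble(joint = character(), frame = integer(), s = numeric(),
                   moment = numeric(), k_before = numeric(), k_after = numeric())

  structure(list(frames = frames,
                 summary = summarize_run(frames, yield_log, config, mass),
                 yield_log = yield_log,
                 reference = ref, config = config, mass = mass),
            class = "squat_sim")
}

# Table-2-shaped summary row: extrema of the per-frame series
summarize_run <- function(frames, yield_log, config, mass) {
  m <- config$motion
  peak <- function(group) {
    cols <- paste0("moment_", grep(group, JOINT_NAMES, value = TRUE))
    max(abs(as.matrix(frames[cols])))
  }
  tibble::tibble(
    mass = mass,
    max_backshift = m$xp0 - min(frames$xp),
    max_drop = m$zp0 - min(frames$zp),
    max_pitch_deg = rad2deg(max(frames$theta_t)),
    peak_moment_ankle = peak("ankle"),
    peak_moment_knee = peak("knee"),
    peak_moment_hip = peak("hip"),
    peak_moment_torso = peak("torso"),
    max_demand_util = max(as.matrix(frames[paste0("demand_", JOINT_NAMES)])),
    max_bounded_util = max(as.matrix(frames[paste0("bounded_", JOINT_NAMES)])),
    n_yield = nrow(yield_log))
}

#' @export
print.squat_sim <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<squat_sim> %d frames, barbell %g kg\n", nrow(x$frames), x$mass))
  cat(sprintf("  max pelvis backshift %.3f m, drop %.3f m, torso pitch %.1f deg\n",
              s$max_backshift, s$max_drop, s$max_pitch_deg))
  cat(sprintf("  peak |moment| (N m): ankle %.1f, knee %.1f, hip %.1f, torso %.1f\n",
              s$peak_moment_ankle, s$peak_moment_knee, s$peak_moment_hip,
              s$peak_moment_torso))
  cat(sprintf("  max utilization: demand %.2f, bounded %.2f; %d yield event(s)\n",
              s$max_demand_util, s$max_bounded_util, s$n_yield))
  invisible(x)
}

#' Sweep a set of barbell masses
#'
#' Runs [run_simulation()] independently for each mass (joint states are
#' reset between load cases: each mass is an independent experiment over
#' the same reference trajectory) and stacks the per-load summaries into
#' a load-response table.  A failing load case is reported and skipped;
#' the remaining cases still run.
#'
#' @param config A [squat_config()].
#' @param masses Barbell masses (kg); defaults to `config$masses`.
#' @return Object of class `squat_sweep`: list with `summary` (tibble,
#'   one row per mass), `sims` (named list of `squat_sim`), `config`.
#' @examples
#' \donttest{
#' sw <- sweep_loads(squat_config(nSteps = 10), masses = c(0, 100))
#' sw$summary
#' }
#' @export
sweep_loads <- function(config, masses = config$masses) {
  stopifnot(length(masses) >= 1)
  sims <- purrr::map(masses, function(mb) {
    tryCatch(run_simulation(config, mass = mb),
             error = function(e) {
               warning(sprintf("load case %g kg failed: %s", mb,
                               conditionMessage(e)), call. = FALSE)
               NULL
             })
  })
  names(sims) <- paste0(masses, "kg")
  ok <- !vapply(sims, is.null, logical(1))
  if (!any(ok)) stop("all load cases failed", call. = FALSE)
  structure(list(summary = dplyr::bind_rows(purrr::map(sims[ok], "summary")),
                 sims = sims[ok], config = config),
            class = "squat_sweep")
}

#' @export
print.squat_sweep <- function(x, ...) {
  cat(sprintf("<squat_sweep> %d load case(s)\n", nrow(x$summary)))
  print(x$summary)
  invisible(x)
}
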