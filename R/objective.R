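# Per-frame objective and constrained minimization ------------------------
#
# At each motion frame the corrected posture minimizes
#
#     Pi(q) = Pi_track + Pi_joint + Pi_ext
#
# over the five generalized coordinates, within a box of coordinate bounds
# and subject to kinematic reachability of both legs (hip-to-ankle planar
# distance inside the [|Ls-Lf|, Ls+Lf] annulus with margin eps).

#' Gravitational potential of the barbell
#'
#' The barbell weight `Wb = mb g` is split equally between the two
#' shoulder points, so the external potential is
#' `Wb/2 * (zSL + zSR)`.
#'
#' @param pose A [forward_pose()] result.
#' @param Wb Barbell weight (N).
#' @return Potential energy (N m).
#' @export
external_potential <- function(pose, Wb) {
  Wb / 2 * (pose$shoulder_L[3] + pose$shoulder_R[3])
}

#' Quadratic tracking term
#'
#' `1/2 (q - q_ref)' K (q - q_ref)` with a diagonal weight matrix; the
#' resistance of the corrected posture to deviating from the intended
#' kinematic motion.
#'
#' @param q,q_ref Generalized-coordinate vectors (length 5).
#' @param weights Diagonal weights ordered (`xp`, `zp`, `psi_p`, `phi_p`,
#'   `theta_t`): N/m for translations, N m/rad for rotations.
#' @return Energy (N m), non-negative.
#' @export
tracking_term <- function(q, q_ref, weights) {
  d <- as.numeric(q) - as.numeric(q_ref)
  0.5 * sum(weights * d^2)
}

# per-frame optimization context shared by the objective, the constraints and
# the solver
frame_context <- function(q_ref, theta_ref, states, config, Wb) {
  m <- config$bounds$translation_margin
  rl <- deg2rad(config$bounds$rotation_limit_deg)
  q_ref <- as_coords(q_ref)
  list(q_ref = q_ref,
       theta_ref = as.numeric(theta_ref),
       states = states,
       weights = as.numeric(config$weights),
       Wb = Wb,
       anthro = config$anthro,
       eps = config$solver$feasibility_margin,
       ik_tol = config$solver$ik_tol,
       lower = c(q_ref[["xp"]] - m, q_ref[["zp"]] - m, -rl, -rl, -rl),
       upper = c(q_ref[["xp"]] + m, q_ref[["zp"]] + m,  rl,  rl,  rl),
       solver = config$solver)
}

#' Reachability inequality residuals
#'
#' For each leg, two residuals that must be non-negative for a feasible
#' posture: `(Ls + Lf - eps) - d` and `d - (|Ls - Lf| + eps)`, where `d`
#' is the planar hip-to-ankle distance in that leg's local plane and
#' `eps` is the feasibility margin.
#'
#' @inheritParams pelvis_frame
#' @param eps Feasibility margin (m).
#' @return Named numeric of length 4 (`L_outer`, `L_inner`, `R_outer`,
#'   `R_inner`); all `>= 0` iff `q` is feasible with margin.
#' @export
feasibility_constraints <- function(q, anthro, eps = 1e-6) {
  pf <- pelvis_frame(q, anthro)
  Ls <- anthro$L_shank; Lf <- anthro$L_thigh
  res_side <- function(hip, ankle, alpha) {
    loc <- project_hip_to_leg_plane(hip, ankle, alpha)
    d <- sqrt(sum(loc^2))
    c(outer = (Ls + Lf - eps) - d, inner = d - (abs(Ls - Lf) + eps))
  }
  rl <- res_side(pf$hip_L, anthro$ankle_L, anthro$foot_yaw_L)
  rr <- res_side(pf$hip_R, anthro$ankle_R, anthro$foot_yaw_R)
  c(L_outer = rl[["outer"]], L_inner = rl[["inner"]],
    R_outer = rr[["outer"]], R_inner = rr[["inner"]])
}

#' Total per-frame objective with component breakdown
#'
#' @inheritParams pelvis_frame
#' @param ctx Frame context: list with `q_ref`, `theta_ref` (7 reference
#'   joint angles), `states` (joint-state tibble), `weights`, `Wb`,
#'   `anthro` and tolerances, as assembled internally by
#'   [run_simulation()].
#' @return List with `tracking`, `joint`, `external` and `total` (N m).
#' @export
total_objective <- function(q, ctx) {
  pose <- forward_pose(q, ctx$anthro, ik_tol = ctx$ik_tol)
  theta <- extract_joint_angles(pose, q, ctx$anthro)
  dtheta <- as.numeric(theta) - ctx$theta_ref
  tr <- tracking_term(q, ctx$q_ref, ctx$weights)
  jt <- total_joint_energy(dtheta, ctx$states)
  ex <- external_potential(pose, ctx$Wb)
  list(tracking = tr, joint = jt, external = ex, total = tr + jt + ex)
}

# scalar objective for the solver: infeasible trial points get a large finite
# penalty growing with the constraint violation, so line searches recover
penalized_objective <- function(ctx) {
  function(q) {
    g <- feasibility_constraints(q, ctx$anthro, ctx$eps)
    viol <- -pmin(g, 0)
    if (any(viol > 0)) return(1e8 * (1 + sum(viol)))
    total_objective(q, ctx)$total
  }
}

#' Objective gradient (central finite differences)
#'
#' Gradient of the penalized per-frame objective by central differences
#' with per-coordinate step `h_i = step * max(1, |q_i|)`.  With five
#' degrees of freedom a finite-difference gradient is accurate and cheap;
#' it is the gradient supplied to the solver.
#'
#' @inheritParams total_objective
#' @param step Relative step size.
#' @return Numeric length-5 gradient.
#' @export
objective_gradient <- function(q, ctx, step = 1e-7) {
  f <- penalized_objective(ctx)
  q <- as.numeric(q)
  vapply(seq_along(q), function(i) {
    h <- step * max(1, abs(q[i]))
    qp <- q; qp[i] <- q[i] + h
    qm <- q; qm[i] <- q[i] - h
    (f(qp) - f(qm)) / (2 * h)
  }, numeric(1))
}

#' Minimize the per-frame objective
#'
#' Bounded, feasibility-constrained local minimization of the tracking +
#' joint-energy + gravitational objective, warm-started from `q_init`
#' (the previous frame's solution in the frame-by-frame scheme).  Uses a
#' gradient-based quasi-Newton solver ([stats::nlminb()], PORT) with box
#' bounds; the leg-reachability inequalities are enforced by a large
#' finite penalty on infeasible trial points plus a post-check of the
#' accepted solution.  Convergence is declared when the relative change
#' of the objective falls below the configured tolerance.
#'
#' @param q_ref Reference coordinates of the frame.
#' @param q_init Feasible starting point (warm start).
#' @param ctx Frame context (see [total_objective()]).
#' @return List with `q` (the corrected coordinates), `objective` (the
#'   [total_objective()] breakdown at the solution) and `report` (list:
#'   `converged`, `iterations`, `evaluations`, `message`, plus
#'   `feasible`, the post-checked reachability flag).
#' @export
minimize_frame <- function(q_ref, q_init, ctx) {
  f <- penalized_objective(ctx)
  q0 <- pmin(pmax(as.numeric(q_init), ctx$lower), ctx$upper)
  fit <- nlminb(start = q0, objective = f,
                gradient = function(q) objective_gradient(q, ctx),
                lower = ctx$lower, upper = ctx$upper,
                control = list(rel.tol = ctx$solver$rel_tol,
                               iter.max = ctx$solver$max_iter,
                               eval.max = 4L * ctx$solver$max_iter))
  # keep the best of (solver iterate, warm start, reference): the reference is
  # always a feasible candidate, so this guarantees Pi(q*) <= Pi(q_ref) and
  # makes the zero-load solution coincide with the reference exactly
  qr <- as.numeric(ctx$q_ref)
  cand <- list(qr, fit$par, q0) # reference first: preferred on exact ties
  vals <- c(f(qr), fit$objective, f(q0))
  qs <- cand[[which.min(vals)]]
  g <- feasibility_constraints(qs, ctx$anthro, ctx$eps)
  # PORT may report "false convergence" when started at (or numerically on) the
  # minimizer; a vanishing projected gradient is accepted as converged
  converged <- fit$convergence == 0
  if (!converged) {
    gr <- objective_gradient(qs, ctx)
    at_lo <- qs <= ctx$lower + 1e-12
    at_hi <- qs >= ctx$upper - 1e-12
    proj <- ifelse(at_lo, pmin(gr, 0), ifelse(at_hi, pmax(gr, 0), gr))
    converged <- max(abs(proj)) < 1e-4 * (1 + abs(fit$objective))
  }
  list(q = setNames(qs, COORD_NAMES),
       objective = total_objective(qs, ctx),
       report = list(converged = converged,
                     iterations = fit$iterations,
                     evaluations = fit$evaluations,
                     message = fit$message,
                     feasible = all(g >= 0)))
}
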