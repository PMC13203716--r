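# shared fixtures and independent oracles (built in code, no stored data)

deg2rad <- function(x) x * pi / 180

# small, fast configs for module tests
tiny_config <- function(n_steps = 8, ...) squat_config(nSteps = n_steps, ...)

symmetric_config <- function(n_steps = 40, ...)
  squat_config(pelvis_yaw_max = 0, pelvis_tilt_x_max = 0, nSteps = n_steps, ...)

# independent inverse-kinematics oracle: scan the shank circle for knee
# candidates minimizing | |knee - hip| - Lf |, golden-section refined, then
# take the anterior (largest local x) root
oracle_knee <- function(xH, zH, Ls, Lf) {
  g <- function(t) abs(sqrt((Ls * sin(t) - xH)^2 + (Ls * cos(t) - zH)^2) - Lf)
  ts <- seq(-pi, pi, by = 1e-3)
  vals <- g(ts)
  n <- length(ts)
  is_min <- vals <= c(Inf, vals[-n]) & vals <= c(vals[-1], Inf)
  best <- NULL
  for (i in which(is_min)) {
    opt <- stats::optimize(g, c(ts[max(i - 1, 1)], ts[min(i + 1, n)]),
                           tol = 1e-9)
    if (opt$objective < 1e-6) {
      x <- Ls * sin(opt$minimum)
      if (is.null(best) || x > best[["xK"]])
        best <- c(xK = x, zK = Ls * cos(opt$minimum))
    }
  }
  best
}

# random planar hip positions strictly inside the reachable annulus
random_reachable_hips <- function(n, Ls, Lf, margin = 0.01) {
  d <- runif(n, abs(Ls - Lf) + margin, Ls + Lf - margin)
  a <- runif(n, -pi, pi)
  cbind(d * sin(a), d * cos(a))
}

# random feasible generalized coordinates: perturb the reference at a random
# motion parameter and keep draws satisfying the reachability margin
random_feasible_points <- function(config, n,
                                   trans_sd = 0.03, rot_sd = 0.08) {
  out <- vector("list", n)
  i <- 0L
  while (i < n) {
    s <- runif(1)
    q <- reference_coords(s, config$motion) +
      c(rnorm(2, 0, trans_sd), rnorm(3, 0, rot_sd))
    g <- feasibility_constraints(q, config$anthro,
                                 eps = config$solver$feasibility_margin)
    if (all(g >= 0)) {
      i <- i + 1L
      out[[i]] <- list(q = q, s = s)
    }
  }
  out
}

# frame optimization context at motion parameter s (elastic joint states)
context_at <- function(config, s, mass) {
  q_ref <- reference_coords(s, config$motion)
  pose <- forward_pose(q_ref, config$anthro)
  theta_ref <- as.numeric(extract_joint_angles(pose, q_ref, config$anthro))
  squatsim:::frame_context(q_ref, theta_ref, joint_states_init(config),
                           config, mass * config$gravity)
}

# central-difference gradient oracle at fixed step (independent of the
# implementation's adaptive-step gradient)
fd_gradient <- function(f, q, h = 1e-6) {
  vapply(seq_along(q), function(i) {
    qp <- q; qp[i] <- q[i] + h
    qm <- q; qm[i] <- q[i] - h
    (f(qp) - f(qm)) / (2 * h)
  }, numeric(1))
}
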