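cfg <- tiny_config()
anthro <- cfg$anthro

test_that("elementary rotations are proper and compose into the pelvis frame", {
  expect_equal(rotation_z(0), diag(3))
  expect_equal(rotation_x(0), diag(3))
  expect_equal(as.numeric(rotation_z(pi / 2) %*% c(1, 0, 0)), c(0, 1, 0))

  set.seed(11)
  for (a in runif(100, -2 * pi, 2 * pi)) {
    for (R in list(rotation_z(a), rotation_x(a))) {
      expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
      expect_equal(det(R), 1, tolerance = 1e-12)
    }
  }
  q <- c(0.1, 0.8, 0.3, -0.2, 0.1)
  pf <- pelvis_frame(q, anthro)
  expect_equal(pf$Rp, rotation_z(0.3) %*% rotation_x(-0.2), tolerance = 1e-15)
})

test_that("pelvis frame places the hip centers at half pelvis width", {
  q0 <- c(0, 0.88, 0, 0, 0)
  pf <- pelvis_frame(q0, anthro)
  expect_equal(pf$pp, c(0, 0, 0.88))
  expect_equal(pf$hip_L, pf$pp + c(0, 0.14, 0))

  set.seed(21)
  for (i in 1:20) {
    q <- c(runif(1, -0.3, 0.3), runif(1, 0.3, 0.9), runif(3, -0.5, 0.5))
    pf <- pelvis_frame(q, anthro)
    expect_equal(sqrt(sum((pf$hip_L - pf$hip_R)^2)), 0.28, tolerance = 1e-12)
  }

  # obliquity of 90 deg tips the transverse axis vertical
  pf <- pelvis_frame(c(0, 0.88, 0, pi / 2, 0), anthro)
  expect_equal(pf$hip_L - pf$pp, c(0, 0, 0.14), tolerance = 1e-12)
})

test_that("hip projection into the local leg plane", {
  expect_equal(unname(project_hip_to_leg_plane(c(0, 0, 0.9), c(0, 0, 0), 0.7)),
               c(0, 0.9))
  p <- project_hip_to_leg_plane(c(0.1, 0.02, 0.8), c(0, 0, 0), deg2rad(15))
  expect_equal(unname(p), c(0.10176896, 0.8), tolerance = 1e-7)
  expect_equal(unname(project_hip_to_leg_plane(c(1, 0, 0), c(0, 0, 0), 0)),
               c(1, 0))
})

test_that("reachability annulus", {
  expect_true(is_reachable(0.45, 0.45, 0.45, 0.45))
  expect_false(is_reachable(0, 0.95, 0.45, 0.45))
  expect_true(is_reachable(0, 0, 0.45, 0.45)) # degenerate equal-length boundary
})

test_that("knee circle intersection takes the anterior branch", {
  k <- solve_knee(0.45, 0.45, 0.45, 0.45)
  expect_equal(unname(k), c(0.45, 0), tolerance = 1e-9)
  # fully extended tangent case: unique solution
  k <- solve_knee(0, 0.90, 0.45, 0.45)
  expect_equal(unname(k), c(0, 0.45), tolerance = 1e-9)
  expect_error(solve_knee(0, 0.95, 0.45, 0.45), "unreachable")

  set.seed(31)
  hips <- random_reachable_hips(50, 0.45, 0.45)
  for (i in seq_len(nrow(hips))) {
    k <- solve_knee(hips[i, 1], hips[i, 2], 0.45, 0.45)
    expect_equal(k[["xK"]]^2 + k[["zK"]]^2, 0.45^2, tolerance = 1e-9)
    expect_equal((hips[i, 1] - k[["xK"]])^2 + (hips[i, 2] - k[["zK"]])^2,
                 0.45^2, tolerance = 1e-9)
  }
})

test_that("solve_knee agrees with the brute-force circle-scan oracle", {
  set.seed(41)
  hips <- random_reachable_hips(200, 0.45, 0.45)
  for (i in seq_len(nrow(hips))) {
    ours <- solve_knee(hips[i, 1], hips[i, 2], 0.45, 0.45)
    ref <- oracle_knee(hips[i, 1], hips[i, 2], 0.45, 0.45)
    expect_lt(max(abs(ours - ref)), 1e-6)
  }
  # unequal segment lengths too
  hips <- random_reachable_hips(50, 0.45, 0.40)
  for (i in seq_len(nrow(hips))) {
    ours <- solve_knee(hips[i, 1], hips[i, 2], 0.45, 0.40)
    ref <- oracle_knee(hips[i, 1], hips[i, 2], 0.45, 0.40)
    expect_lt(max(abs(ours - ref)), 1e-6)
  }
})

test_that("forward pose satisfies the rigid-segment invariants", {
  q_up <- c(0, 0.88, 0, 0, 0)
  pose <- forward_pose(q_up, anthro)
  expect_equal(pose$shoulder_center, c(0, 0, 0.88 + 0.60), tolerance = 1e-12)

  pose30 <- forward_pose(c(0, 0.7, 0, 0, pi / 6), anthro)
  expect_equal(pose30$torso_dir, c(0.5, 0, sqrt(3) / 2), tolerance = 1e-12)

  set.seed(51)
  pts <- random_feasible_points(cfg, 200)
  for (p in pts) {
    pose <- forward_pose(p$q, anthro)
    seg <- function(a, b) sqrt(sum((a - b)^2))
    expect_equal(seg(pose$knee_L, pose$ankle_L), anthro$L_shank, tolerance = 1e-9)
    expect_equal(seg(pose$knee_R, pose$ankle_R), anthro$L_shank, tolerance = 1e-9)
    # thigh length is preserved in each leg's local plane (the hip generically
    # lies slightly out of that plane, so the 3-D hip-knee distance exceeds it)
    for (side in c("L", "R")) {
      loc <- pose$leg_local[[side]]
      expect_equal((loc[["xH"]] - loc[["xK"]])^2 + (loc[["zH"]] - loc[["zK"]])^2,
                   anthro$L_thigh^2, tolerance = 1e-9)
      expect_gte(seg(pose[[paste0("hip_", side)]], pose[[paste0("knee_", side)]]),
                 anthro$L_thigh - 1e-9)
    }
    expect_equal(seg(pose$shoulder_L, pose$shoulder_R), 0.38, tolerance = 1e-9)
    expect_equal(seg(pose$shoulder_center, pose$pp), anthro$L_torso,
                 tolerance = 1e-12)
    expect_equal(sqrt(sum(pose$torso_dir^2)), 1, tolerance = 1e-12)
    expect_equal(t(pose$Rp) %*% pose$Rp, diag(3), tolerance = 1e-12)
  }

  expect_error(forward_pose(c(0, 1.2, 0, 0, 0), anthro), "left")
})

test_that("joint angle extraction follows the local-vertical convention", {
  # fully extended vertical legs: every measure is zero
  cfg0 <- squat_config(leg_clearance = 0)
  q_up <- c(0, 0.90, 0, 0, 0)
  pose <- forward_pose(q_up, cfg0$anthro)
  theta <- extract_joint_angles(pose, q_up, cfg0$anthro)
  expect_equal(unname(as.numeric(theta)), rep(0, 7), tolerance = 1e-9)

  # horizontal shank + vertical thigh from a constructed local solution
  fake <- list(leg_local = list(L = c(xH = 0.45, zH = 0.45, xK = 0.45, zK = 0),
                                R = c(xH = 0.45, zH = 0.45, xK = 0.45, zK = 0)))
  th <- extract_joint_angles(fake, c(0, 0.8, 0, 0, 0), anthro)
  expect_equal(th[["ankle_L"]], pi / 2)
  expect_equal(th[["knee_L"]], pi / 2)
  seg <- attr(th, "segment_angles")
  expect_equal(seg[["thigh_L"]], 0)

  # torso measure is pitch minus obliquity, exactly
  th2 <- extract_joint_angles(fake, c(0, 0.8, 0, deg2rad(10), deg2rad(40)),
                              anthro)
  expect_equal(th2[["torso"]], deg2rad(30))

  # composite identities hold by construction on random poses
  set.seed(61)
  for (p in random_feasible_points(cfg, 25)) {
    pose <- forward_pose(p$q, anthro)
    th <- extract_joint_angles(pose, p$q, anthro)
    sa <- attr(th, "segment_angles")
    expect_equal(th[["knee_L"]], sa[["shank_L"]] - sa[["thigh_L"]])
    expect_equal(th[["hip_L"]], unname(sa[["thigh_L"]] - p$q[4]))
    expect_equal(th[["hip_R"]], unname(sa[["thigh_R"]] - p$q[4]))
  }
})
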