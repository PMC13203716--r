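test_that("zero-load run reproduces the reference motion exactly", {
  cfg <- tiny_config(n_steps = 12)
  sim <- run_simulation(cfg, mass = 0)
  expect_s3_class(sim, "squat_sim")
  expect_equal(nrow(sim$frames), 12)

  # corrected posture coincides with the reference at every frame
  for (col in c("xp", "zp", "psi_p", "phi_p", "theta_t"))
    expect_lt(max(abs(sim$frames[[col]] - sim$frames[[paste0(col, "_ref")]])),
              1e-6)

  s <- sim$summary
  expect_equal(s$max_backshift, 0.18, tolerance = 1e-5)
  expect_equal(s$max_drop, 0.60, tolerance = 1e-5)
  expect_equal(s$max_pitch_deg, 30, tolerance = 1e-4)
  expect_equal(s$n_yield, 0)

  # summary values are the extrema of the per-frame series
  expect_equal(s$max_backshift, cfg$motion$xp0 - min(sim$frames$xp))
  expect_equal(s$max_drop, cfg$motion$zp0 - min(sim$frames$zp))
  expect_equal(s$peak_moment_knee,
               max(abs(c(sim$frames$moment_knee_L, sim$frames$moment_knee_R))))
})

test_that("simulation is deterministic and moments respect capacities", {
  cfg <- tiny_config(n_steps = 10)
  a <- run_simulation(cfg, mass = 100)
  b <- run_simulation(cfg, mass = 100)
  expect_identical(a$frames, b$frames)
  expect_identical(a$summary, b$summary)

  states <- joint_states_init(cfg)
  mom <- as.matrix(a$frames[paste0("moment_",
                                   c("ankle_L", "knee_L", "hip_L", "ankle_R",
                                     "knee_R", "hip_R", "torso"))])
  expect_true(all(abs(t(mom)) <= states$My))
  # demand utilization dominates the bounded one everywhere
  dem <- as.matrix(a$frames[grep("^demand_", names(a$frames))])
  bnd <- as.matrix(a$frames[grep("^bounded_", names(a$frames))])
  expect_true(all(dem >= bnd - 1e-12))
})

test_that("symmetric stance at zero load has no left/right bias", {
  # at zero load the corrected motion is the (mirror-symmetric) reference, so
  # any left/right difference would be a numerical bias of the pipeline
  cfg <- symmetric_config(n_steps = 12)
  sim <- run_simulation(cfg, mass = 0)
  for (g in c("ankle", "knee", "hip")) {
    expect_lt(max(abs(sim$frames[[paste0("moment_", g, "_L")]] -
                      sim$frames[[paste0("moment_", g, "_R")]])), 1e-9)
  }
  expect_equal(max(abs(sim$frames$psi_p)), 0)
  expect_equal(max(abs(sim$frames$phi_p)), 0)
})

test_that("under load the model develops pelvic roll from symmetric inputs", {
  # the printed angular measures subtract the pelvic obliquity with the same
  # sign in every composite joint measure, so a loaded (deviated) posture can
  # relieve sagittal joint energy through a small pelvic roll: mirror symmetry
  # of the corrected posture is a zero-load property only (methods vignette)
  cfg <- symmetric_config(n_steps = 12)
  sim <- run_simulation(cfg, mass = 100)
  expect_gt(max(abs(sim$frames$phi_p)), 1e-4)
})

test_that("yield events are single, permanent and correctly logged", {
  # heavy load drives the torso joint past its yield fraction mid-descent
  cfg <- symmetric_config(n_steps = 20)
  sim <- run_simulation(cfg, mass = 140)
  yl <- sim$yield_log
  expect_gte(nrow(yl), 1)
  expect_false(any(duplicated(yl$joint)))
  expect_true(all(abs(yl$moment) >= 0.95 * 250 - 1e-9 |
                    yl$joint != "torso"))
  expect_true(all(yl$k_after / yl$k_before >= 0.05 &
                    yl$k_after / yl$k_before <= 0.10))
  expect_true("torso" %in% yl$joint)

  # stiffness used in the recorded demand is a non-increasing step function:
  # demand/|delta| recovers k/My per frame
  fr <- sim$frames
  nz <- abs(fr$delta_torso) > 1e-9
  k_series <- fr$demand_torso[nz] / abs(fr$delta_torso[nz]) * 250
  expect_true(all(diff(k_series) <= 1e-6))
  expect_lte(length(unique(round(k_series, 3))), 2)
})

test_that("warm-start continuity holds below the yield threshold", {
  cfg <- tiny_config(n_steps = 15)
  for (mass in c(0, 60)) {
    sim <- run_simulation(cfg, mass = mass)
    expect_equal(sim$summary$n_yield, 0)
    for (col in c("xp", "zp", "psi_p", "phi_p", "theta_t")) {
      step_ref <- max(abs(diff(sim$frames[[paste0(col, "_ref")]])))
      step_cor <- max(abs(diff(sim$frames[[col]])))
      expect_lte(step_cor, 3 * step_ref + 1e-9)
    }
  }
})

test_that("load sweep stacks independent cases", {
  cfg <- tiny_config(n_steps = 10)
  sw <- sweep_loads(cfg, masses = c(0, 100))
  expect_s3_class(sw, "squat_sweep")
  expect_equal(nrow(sw$summary), 2)
  expect_equal(sw$summary$mass, c(0, 100))

  # joint states reset between loads: the 100 kg case is unaffected by the
  # 0 kg case having run first
  alone <- run_simulation(cfg, mass = 100)
  expect_identical(sw$sims[["100kg"]]$frames, alone$frames)

  # pelvis drop is controlled by the reference in every case
  expect_true(all(abs(sw$summary$max_drop - 0.60) < 0.02))
})

test_that("outputs round-trip through CSV files and the run manifest", {
  cfg <- tiny_config(n_steps = 6)
  sw <- sweep_loads(cfg, masses = c(0, 80))
  out <- withr::local_tempdir()
  paths <- write_outputs(sw, out)
  expect_true(all(file.exists(paths)))

  traj <- readr::read_csv(paths[["trajectory"]], show_col_types = FALSE)
  expect_equal(nrow(traj), 2 * 6)
  expect_equal(max(abs(traj$theta_t_ref)), 30, tolerance = 1e-6) # degrees at the boundary
  smry <- readr::read_csv(paths[["summary"]], show_col_types = FALSE)
  expect_equal(nrow(smry), 2)
  expect_true(all(c("max_backshift", "max_drop", "max_pitch_deg",
                    "peak_moment_hip", "max_demand_util") %in% names(smry)))

  # manifest reproduces the run bit-identically
  man <- read_manifest(paths[["manifest"]])
  sw2 <- sweep_loads(man$config, masses = man$masses)
  expect_identical(sw2$summary, sw$summary)
  expect_identical(sw2$sims[["80kg"]]$frames, sw$sims[["80kg"]]$frames)
})

test_that("tidy and glance accessors and plots", {
  cfg <- tiny_config(n_steps = 6)
  sim <- run_simulation(cfg, mass = 60)
  td <- tidy(sim)
  expect_equal(nrow(td), 6 * 7)
  expect_setequal(unique(td$joint), c("ankle", "knee", "hip", "torso"))
  expect_true(all(td$demand >= td$bounded - 1e-12))
  expect_identical(glance(sim), sim$summary)

  sw <- sweep_loads(cfg, masses = c(0, 60))
  expect_equal(nrow(tidy(sw)), 2 * 6 * 7)
  expect_identical(glance(sw), sw$summary)

  for (type in c("trajectory", "pitch", "moments", "utilization"))
    expect_s3_class(autoplot(sim, type = type), "ggplot")
  expect_s3_class(autoplot(sw), "ggplot")
})

test_that("configuration validation and file I/O", {
  expect_error(squat_config(nSteps = 1), "nSteps")
  expect_error(squat_config(L_shank = -1), "positive")
  expect_error(squat_config(joints = list(elbow = list(My = 10))), "unknown joint group")
  expect_error(squat_config(joints = list(knee = list(ke = 1, kp = 5))), "ke > kp")
  expect_error(squat_config(profile = "linear"))

  cfg <- read_config() # packaged defaults reproduce the published table
  expect_equal(cfg$anthro$L_shank, 0.45)
  expect_equal(cfg$anthro$pelvis_width, 0.28)
  expect_equal(cfg$motion$n_steps, 40L)
  expect_equal(cfg$motion$pitch_max, deg2rad(30))
  expect_equal(cfg$masses, c(0, 60, 100, 140))

  sym <- read_config(default_config_path("symmetric"))
  expect_equal(sym$motion$yaw_max, 0)

  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(L_shank = 0.45, shank_len = 0.4), bad,
                       auto_unbox = TRUE)
  expect_error(read_config(bad), "unknown configuration key")
})

test_that("command-line interface runs the reference subcommand", {
  script <- system.file("cli", "squatsim.R", package = "squatsim")
  expect_true(nzchar(script))
  out <- withr::local_tempdir()
  status <- system2(file.path(R.home("bin"), "Rscript"),
                    c(script, "reference", "--frames", "5", "--out", out),
                    stdout = FALSE, stderr = FALSE,
                    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep)))
  expect_identical(status, 0L)
  ref <- readr::read_csv(file.path(out, "reference.csv"), show_col_types = FALSE)
  expect_equal(nrow(ref), 5)
})
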