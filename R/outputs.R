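# CSV / manifest export -----------------------------------------------------

#' Write simulation outputs to a directory
#'
#' Writes plain comma-separated tables (header row, one row per frame)
#' plus a JSON run manifest containing the fully resolved configuration,
#' so a run can be reproduced exactly from its output directory:
#' \describe{
#'   \item{trajectory.csv}{`mass`, `frame`, `s`, reference and corrected
#'     generalized coordinates (angles in degrees), shoulder-center
#'     position.}
#'   \item{moments.csv}{per-frame moments of the seven joints (N m).}
#'   \item{utilization.csv}{per-frame demand and bounded utilizations.}
#'   \item{summary.csv}{one row per load case with the peak-response
#'     metrics (backshift, drop, pitch, peak moments, utilization).}
#'   \item{manifest.json}{resolved configuration (published key names,
#'     degrees at the boundary), masses and package version; see
#'     [read_manifest()].}
#' }
#'
#' @param result A `squat_sim` or `squat_sweep`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_outputs <- function(result, out_dir) {
  if (inherits(result, "squat_sim")) {
    sims <- list(result); config <- result$config
    summary <- result$summary
  } else if (inherits(result, "squat_sweep")) {
    sims <- result$sims; config <- result$config
    summary <- result$summary
  } else stop("result must be a squat_sim or squat_sweep", call. = FALSE)

  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)

  deg_cols <- c("psi_p_ref", "phi_p_ref", "theta_t_ref",
                "psi_p", "phi_p", "theta_t")
  traj <- dplyr::bind_rows(purrr::map(sims, function(sim)
    dplyr::mutate(
      dplyr::select(sim$frames, "frame", "s",
                    dplyr::all_of(c(paste0(COORD_NAMES, "_ref"), COORD_NAMES)),
                    "shoulder_x", "shoulder_z"),
      dplyr::across(dplyr::all_of(deg_cols), rad2deg),
      mass = sim$mass, .before = 1)))
  joint_table <- function(prefix) dplyr::bind_rows(purrr::map(sims, function(sim)
    dplyr::mutate(
      dplyr::select(sim$frames, "frame", "s",
                    dplyr::starts_with(paste0(prefix, "_"))),
      mass = sim$mass, .before = 1)))
  util <- dplyr::bind_rows(purrr::map(sims, function(sim)
    dplyr::mutate(
      dplyr::select(sim$frames, "frame", "s", dplyr::starts_with("demand_"),
                    dplyr::starts_with("bounded_")),
      mass = sim$mass, .before = 1)))

  paths <- c(trajectory = file.path(out_dir, "trajectory.csv"),
             moments = file.path(out_dir, "moments.csv"),
             utilization = file.path(out_dir, "utilization.csv"),
             summary = file.path(out_dir, "summary.csv"),
             manifest = file.path(out_dir, "manifest.json"))
  tryCatch({
    readr::write_csv(traj, paths[["trajectory"]])
    readr::write_csv(joint_table("moment"), paths[["moments"]])
    readr::write_csv(util, paths[["utilization"]])
    readr::write_csv(summary, paths[["summary"]])
    manifest <- list(package = "squatsim",
                     version = as.character(packageVersion("squatsim")),
                     masses = vapply(sims, `[[`, numeric(1), "mass"),
                     config = config_as_keyvalue(config))
    jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }, error = function(e)
    stop("failed writing outputs under ", out_dir, ": ",
         conditionMessage(e), call. = FALSE))
  invisible(paths)
}

#' Rebuild a configuration from a run manifest
#'
#' Reads the `manifest.json` written by [write_outputs()] and
#' reconstructs the [squat_config()] and mass list, so re-running
#' [sweep_loads()] from a manifest reproduces the original outputs
#' exactly (the pipeline is deterministic).
#'
#' @param path Path to a manifest JSON file.
#' @return List with `config` (a `squat_config`) and `masses`.
#' @export
read_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(man$config))
    stop(path, ": not a run manifest (no `config` entry)", call. = FALSE)
  list(config = config_from_list(man$config, context = path),
       masses = as.numeric(man$masses))
}
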