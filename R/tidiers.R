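# broom-style accessors ------------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-joint series of a simulation
#'
#' One row per frame and joint: deviation from the reference angle,
#' moment, demand and bounded utilizations, with the joint name split
#' into `joint` (ankle/knee/hip/torso) and `side` (L/R/NA).
#'
#' @param x A `squat_sim`.
#' @param ... Unused.
#' @return A tibble with columns `mass`, `frame`, `s`, `joint`, `side`,
#'   `delta_theta`, `moment`, `demand`, `bounded`.
#' @export
tidy.squat_sim <- function(x, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(x$frames, "frame", "s",
                  dplyr::matches("^(delta|moment|demand|bounded)_")),
    cols = -c("frame", "s"),
    names_to = c("quantity", "joint"),
    names_pattern = "^(delta|moment|demand|bounded)_(.*)$")
  wide <- tidyr::pivot_wider(long, names_from = "quantity",
                             values_from = "value")
  wide <- dplyr::rename(wide, delta_theta = "delta")
  wide$side <- ifelse(grepl("_L$", wide$joint), "L",
                      ifelse(grepl("_R$", wide$joint), "R", NA_character_))
  wide$joint <- sub("_[LR]$", "", wide$joint)
  dplyr::mutate(
    dplyr::relocate(wide, "joint", "side", .after = "s"),
    mass = x$mass, .before = 1)
}

#' One-row summary of a simulation
#'
#' @param x A `squat_sim`.
#' @param ... Unused.
#' @return The peak-response summary tibble (see [run_simulation()]).
#' @export
glance.squat_sim <- function(x, ...) x$summary

#' Tidy per-joint series of a load sweep
#'
#' @param x A `squat_sweep`.
#' @param ... Unused.
#' @return Stacked [tidy.squat_sim()] tibbles, one block per mass.
#' @export
tidy.squat_sweep <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$sims, tidy))
}

#' Load-response summary of a sweep
#'
#' @param x A `squat_sweep`.
#' @param ... Unused.
#' @return One summary row per load case.
#' @export
glance.squat_sweep <- function(x, ...) x$summary
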