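# ggplot2 visualisations -----------------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulation result
#'
#' @param object A `squat_sim`.
#' @param type One of `"trajectory"` (pelvis path, reference vs
#'   corrected), `"pitch"` (torso pitch over the cycle), `"moments"`
#'   (joint moment histories) or `"utilization"` (demand utilization with
#'   the yield threshold).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.squat_sim <- function(object,
                               type = c("trajectory", "pitch", "moments",
                                        "utilization"),
                               ...) {
  type <- match.arg(type)
  fr <- object$frames
  lab_mass <- sprintf("barbell %g kg", object$mass)
  if (type == "trajectory") {
    df <- dplyr::bind_rows(
      tibble::tibble(x = fr$xp_ref, z = fr$zp_ref, series = "reference"),
      tibble::tibble(x = fr$xp, z = fr$zp, series = "corrected"))
    return(ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$z,
                                            colour = .data$series)) +
             ggplot2::geom_path() + ggplot2::geom_point(size = 0.8) +
             ggplot2::labs(x = "pelvis x [m]", y = "pelvis z [m]",
                           title = paste("Pelvis trajectory,", lab_mass),
                           colour = NULL))
  }
  if (type == "pitch") {
    df <- tidyr::pivot_longer(
      dplyr::transmute(fr, s = .data$s,
                       reference = rad2deg(.data$theta_t_ref),
                       corrected = rad2deg(.data$theta_t)),
      -"s", names_to = "series", values_to = "pitch")
    return(ggplot2::ggplot(df, ggplot2::aes(.data$s, .data$pitch,
                                            colour = .data$series)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "motion parameter s", y = "torso pitch [deg]",
                           title = paste("Torso pitch,", lab_mass),
                           colour = NULL))
  }
  long <- tidy(object)
  long$label <- ifelse(is.na(long$side), long$joint,
                       paste(long$joint, long$side))
  if (type == "moments") {
    ggplot2::ggplot(long, ggplot2::aes(.data$s, .data$moment,
                                       colour = .data$label)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "motion parameter s", y = "joint moment [N m]",
                    title = paste("Joint moment histories,", lab_mass),
                    colour = "joint")
  } else {
    ggplot2::ggplot(long, ggplot2::aes(.data$s, .data$demand,
                                       colour = .data$label)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 1, linetype = 2) +
      ggplot2::labs(x = "motion parameter s", y = "demand utilization [-]",
                    title = paste("Joint utilization,", lab_mass),
                    colour = "joint")
  }
}

#' Plot peak responses across a load sweep
#'
#' Peak response measures (pelvis backshift, torso pitch, per-group peak
#' moments, maximum demand utilization) as functions of barbell mass.
#'
#' @param object A `squat_sweep`.
#' @param ... Unused.
#' @return A ggplot object (facetted by measure).
#' @export
autoplot.squat_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(object$summary, -"mass",
                            names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$mass, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "barbell mass [kg]", y = NULL,
                  title = "Peak responses vs barbell mass")
}

#' Quick plot helpers
#'
#' Thin wrappers over [autoplot.squat_sim()].
#'
#' @param sim A `squat_sim`.
#' @return A ggplot object.
#' @export
plot_moments <- function(sim) autoplot(sim, type = "moments")

#' @rdname plot_moments
#' @export
plot_utilization <- function(sim) autoplot(sim, type = "utilization")

#' @rdname plot_moments
#' @export
plot_trajectory <- function(sim) autoplot(sim, type = "trajectory")
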