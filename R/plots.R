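# ggplot2 figures for stimuli, population vectors, cohorts, trajectories
# and parameter sweeps.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_path geom_point
#'   geom_tile geom_contour coord_equal coord_polar labs theme_minimal
#'   scale_fill_viridis_c annotate geom_segment arrow unit geom_hline
NULL

#' @export
ggplot2::autoplot

circle_df <- function(r = 1, n = 361) {
  tibble(x = r * cos_deg(seq(0, 360, length.out = n)),
         y = r * sin_deg(seq(0, 360, length.out = n)))
}

#' Plot a stimulus pattern
#'
#' @param object an `urchin_stimulus`.
#' @param polar draw on the arena wall (polar) rather than as a linear
#'   profile.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.urchin_stimulus <- function(object, polar = FALSE, ...) {
  p <- ggplot(object, aes(x = .data$angle_deg, y = .data$intensity)) +
    geom_line() +
    labs(x = "wall angle (deg)", y = "intensity (1 - ink)",
         title = sprintf("%s stimulus%s", attr(object, "family"),
                         if (is.na(attr(object, "phi_stim"))) "" else
                           sprintf(", phi_stim = %g deg",
                                   attr(object, "phi_stim")))) +
    theme_minimal()
  if (polar) p <- p + coord_polar(start = -pi / 2, direction = -1)
  p
}

#' Plot population-vector tips across orientations
#'
#' Scatter of the population-vector tips for all orientations, with the
#' detection-threshold circle; vectors outside the circle mean the stimulus
#' is detectable from that orientation.
#'
#' @param pv an `urchin_pv` from [population_vectors()].
#' @return a ggplot.
#' @export
plot_population_vectors <- function(pv) {
  thr <- attr(pv, "theta_p") %||% 5
  ggplot(pv, aes(x = .data$v_x, y = .data$v_y)) +
    geom_path(data = circle_df(thr), aes(x = .data$x, y = .data$y),
              linetype = 2, colour = "blue") +
    geom_point(colour = "red", size = 0.8) +
    coord_equal() +
    labs(x = "v_x", y = "v_y",
         title = sprintf("population vectors: %s %s", attr(pv, "family"),
                         if (is.na(attr(pv, "phi_stim"))) "" else
                           sprintf("%g deg", attr(pv, "phi_stim")))) +
    theme_minimal()
}

#' Arena plot of a cohort's final positions
#'
#' Final bearings of every subject on the arena wall plus the circular mean
#' vector (scaled to the arena radius).
#'
#' @param object an `urchin_cohort`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.urchin_cohort <- function(object, ...) {
  b <- object$bearings
  pts <- tibble(x = cos_deg(b$bearing_deg), y = sin_deg(b$bearing_deg))
  cm <- circular_mean(b$bearing_deg)
  ggplot() +
    geom_path(data = circle_df(1), aes(x = .data$x, y = .data$y)) +
    geom_point(data = pts, aes(x = .data$x, y = .data$y),
               colour = "steelblue", alpha = 0.5) +
    geom_segment(aes(x = 0, y = 0, xend = cm$r_x, yend = cm$r_y),
                 colour = "red",
                 arrow = arrow(length = unit(0.12, "inches"))) +
    coord_equal() +
    labs(title = sprintf("%s cohort (%s mode): |r_f| = %.3f",
                         object$family, object$mode, cm$length),
         x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot taxis trajectories in the arena
#'
#' @param trajectories a single `urchin_trajectory` or a list of them.
#' @return a ggplot.
#' @export
plot_trajectories <- function(trajectories) {
  if (inherits(trajectories, "urchin_trajectory")) {
    trajectories <- list(trajectories)
  }
  paths <- purrr::imap_dfr(trajectories, function(tr, i) {
    bind_rows(tibble(step = 0L, x = 0, y = 0),
              tr[, c("step", "x", "y")]) %>% mutate(trial = i)
  })
  ggplot(paths, aes(x = .data$x, y = .data$y,
                    group = .data$trial, colour = factor(.data$trial))) +
    geom_path(alpha = 0.7, show.legend = FALSE) +
    geom_path(data = circle_df(1), aes(x = .data$x, y = .data$y),
              inherit.aes = FALSE) +
    coord_equal() +
    labs(x = NULL, y = NULL, title = "simulated taxis trajectories") +
    theme_minimal()
}

#' Heatmap of a v_max parameter sweep
#'
#' Tile map of `v_max` over the (delta_rho, delta) plane with the detection
#' contour at `theta_p`, the `v_max = 4` contour, and the effective
#' acceptance-angle line `delta_rho + 2 delta = 60`.
#'
#' @param object an `urchin_sweep`.
#' @param theta_p detection threshold drawn as a contour.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.urchin_sweep <- function(object, theta_p = 5, ...) {
  cont <- detection_contours(object, levels = c(theta_p, 4))
  p <- ggplot(object, aes(x = .data$delta_rho, y = .data$delta)) +
    geom_tile(aes(fill = .data$v_max)) +
    scale_fill_viridis_c(name = "v_max") +
    geom_line(data = cont$constraint_line,
              aes(x = .data$delta_rho, y = .data$delta),
              colour = "white") +
    labs(x = "acceptance angle delta_rho (deg)",
         y = "location half-width delta (deg)",
         title = sprintf("v_max: %s %g deg", attr(object, "family"),
                         attr(object, "phi_stim"))) +
    theme_minimal()
  if (nrow(cont$contours)) {
    p <- p + geom_path(
      data = cont$contours,
      aes(x = .data$delta_rho, y = .data$delta,
          group = .data$piece, linetype = factor(.data$level)),
      colour = "red"
    ) + labs(linetype = "contour")
  }
  p
}
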