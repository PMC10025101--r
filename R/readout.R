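# Population-vector readout of the oral nerve ring.
#
# Every eONR group votes for its preferred direction (the direction of a
# narrow probe stimulus that maximally increases its activity) with a weight
# equal to its firing rate; the vector sum is the population vector. Its
# length against the threshold theta_p decides detection; its direction is
# the inferred stimulus bearing.

#' Probe-based preferred directions of the eONR groups
#'
#' Presents a 2-degree white bar on a black background at every integer
#' probe direction (animal frame, arena centre), solves the network to its
#' steady state, and assigns each eONR group the probe direction of its
#' maximal response (circular argmax; exact ties are resolved by the
#' circular mean of the tied directions). The map depends only on the model
#' architecture, never on an extended stimulus.
#'
#' @param model an `urchin_model`.
#' @param probe_width width of the white probe bar, degrees.
#' @param probe_step probe direction grid spacing, degrees.
#' @return a tibble of class `urchin_pref_map`: `cell`, `position_deg` (the
#'   group's angular location), `pref_deg` (preferred direction), and the
#'   unit-vector components `z_x`, `z_y`.
#' @export
compute_preferred_directions <- function(model, probe_width = 2,
                                         probe_step = 1) {
  p <- model$params
  dirs <- seq(0, 360 - probe_step, by = probe_step)
  half <- probe_width / 2
  X <- vapply(dirs, function(d) {
    as.numeric(abs(ang_diff(model$grid, d)) <= half)
  }, numeric(length(model$grid)))
  prc_mat <- p$r_max_prc * (model$sens %*% X) / model$sens_rowsum
  sol <- solve_fixed_point(model, as.matrix(prc_mat))
  r <- sol$r_onr # n_onr x n_dirs
  rng <- apply(r, 1, max) - apply(r, 1, min)
  flat <- which(rng < 1e-12)
  if (length(flat)) {
    abort(sprintf(
      "flat probe response: preferred direction undefined for eONR cell(s) %s",
      paste(utils::head(flat, 5), collapse = ", ")
    ))
  }
  pref <- vapply(seq_len(nrow(r)), function(i) {
    ri <- r[i, ]
    at <- which(ri >= max(ri) - 1e-9)
    if (length(at) == 1L) {
      dirs[at]
    } else {
      atan2_deg(mean(sin_deg(dirs[at])), mean(cos_deg(dirs[at])))
    }
  }, numeric(1))
  out <- tibble(
    cell = seq_len(p$n_onr),
    position_deg = model$onr_pos,
    pref_deg = pref,
    z_x = cos_deg(pref),
    z_y = sin_deg(pref)
  )
  structure(out, class = c("urchin_pref_map", class(out)))
}

#' Attach the preferred-direction map to a model
#'
#' Convenience wrapper: computes (or accepts) the probe-based
#' preferred-direction map and stores it in the model, so downstream readout
#' functions do not recompute it.
#'
#' @param model an `urchin_model`.
#' @param pref an existing `urchin_pref_map`, or `NULL` to compute it.
#' @return the model with `$pref` set.
#' @export
#' @examples
#' m <- urchin_model(n_prc = 20, n_onr = 60)
#' m <- with_preferred_directions(m)
with_preferred_directions <- function(model, pref = NULL) {
  model$pref <- pref %||% compute_preferred_directions(model)
  model
}

model_pref <- function(model, pref = NULL) {
  pref %||% model$pref %||% compute_preferred_directions(model)
}

#' Population vector of an eONR activity pattern
#'
#' `v = sum_i r_i * (cos(pref_i), sin(pref_i))` (animal frame).
#'
#' @param r_onr numeric vector of eONR rates.
#' @param map an `urchin_pref_map` with matching cells.
#' @param theta_p detection threshold for the vector length.
#' @return a one-row tibble: `v_x`, `v_y`, `length`, `direction_deg`
#'   (animal frame), `detected` (strictly `length > theta_p`).
#' @export
population_vector <- function(r_onr, map, theta_p = 5) {
  if (length(r_onr) != nrow(map)) {
    abort("`r_onr` and preferred-direction map sizes differ.")
  }
  vx <- sum(r_onr * map$z_x)
  vy <- sum(r_onr * map$z_y)
  len <- sqrt(vx^2 + vy^2)
  tibble(
    v_x = vx, v_y = vy, length = len,
    direction_deg = atan2_deg(vy, vx),
    detected = len > theta_p
  )
}

#' Population vectors across initial orientations
#'
#' Places the animal at the arena centre and computes, for every orientation
#' `psi`, the steady-state network response to the stimulus and its
#' population vector.
#'
#' @param model an `urchin_model`.
#' @param stimulus an `urchin_stimulus`.
#' @param psi orientations in degrees (default all 360 integers).
#' @param pref optional precomputed `urchin_pref_map`.
#' @return a tibble of class `urchin_pv`: one row per orientation with
#'   `psi`, `v_x`, `v_y`, `length`, `direction_deg` (animal frame),
#'   `bearing_deg` (arena frame, i.e. `direction_deg + psi`), `detected`,
#'   `iterations`, `converged`.
#' @export
#' @examples
#' m <- with_preferred_directions(urchin_model(n_prc = 20, n_onr = 60))
#' pv <- population_vectors(m, make_stimulus("dog", 69), psi = c(0, 36))
population_vectors <- function(model, stimulus, psi = 0:359, pref = NULL) {
  map <- model_pref(model, pref)
  p <- model$params
  prc_mat <- prc_matrix_for_orientations(model, stimulus, psi)
  sol <- solve_fixed_point(model, as.matrix(prc_mat))
  vx <- as.vector(crossprod(sol$r_onr, map$z_x))
  vy <- as.vector(crossprod(sol$r_onr, map$z_y))
  len <- sqrt(vx^2 + vy^2)
  out <- tibble(
    psi = psi, v_x = vx, v_y = vy, length = len,
    direction_deg = atan2_deg(vy, vx),
    bearing_deg = wrap_angle(atan2_deg(vy, vx) + psi),
    detected = len > p$theta_p,
    iterations = sol$iterations,
    converged = sol$converged
  )
  structure(out, class = c("urchin_pv", class(out)),
            family = attr(stimulus, "family"),
            phi_stim = attr(stimulus, "phi_stim"),
            theta_p = p$theta_p)
}

#' Maximal population-vector length across orientations
#'
#' The detection summary used in parameter sweeps: the maximum population
#' vector length over all initial orientations of the animal at the arena
#' centre. The stimulus is detectable from some orientation iff
#' `vmax > theta_p`.
#'
#' @inheritParams population_vectors
#' @return scalar `v_max`.
#' @export
vmax_over_orientations <- function(model, stimulus, psi = 0:359,
                                   pref = NULL) {
  max(population_vectors(model, stimulus, psi = psi, pref = pref)$length)
}

#' Detection decision
#'
#' @param v a population-vector row (from [population_vector()] or one row
#'   of [population_vectors()]), or a numeric vector length.
#' @param theta_p detection threshold.
#' @return logical: strictly `length > theta_p`.
#' @export
detect <- function(v, theta_p = 5) {
  len <- if (is.numeric(v)) v else v$length
  len > theta_p
}
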