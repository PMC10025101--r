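# Robustness maps: maximal population-vector length over the
# (acceptance angle, location half-width) parameter plane.

#' Sweep v_max over the (delta_rho, delta) plane
#'
#' For every grid combination the photoreceptor layer is rebuilt, the
#' preferred-direction map recomputed (it depends on both parameters), and
#' the maximal population-vector length over all initial orientations
#' evaluated for the given stimulus. Combinations with `delta >= 36` (which
#' would make neighbouring ambulacral bands overlap) are masked with `NA`.
#'
#' @param family,phi_stim stimulus family and target arc (degrees).
#' @param delta_rho_values acceptance angles to scan, degrees.
#' @param delta_values location half-widths to scan, degrees.
#' @param psi_step orientation grid spacing for the v_max scan, degrees.
#' @param ... further arguments passed to [urchin_model()] (e.g. smaller
#'   layer sizes for quick scans).
#' @return a tibble of class `urchin_sweep`: `delta_rho`, `delta`, `v_max`.
#' @export
vmax_heatmap <- function(family, phi_stim,
                         delta_rho_values = seq(15, 90, length.out = 16),
                         delta_values = seq(5, 20, length.out = 16),
                         psi_step = 1, ...) {
  stim <- make_stimulus(family, phi_stim)
  grid <- tidyr::expand_grid(delta_rho = delta_rho_values,
                             delta = delta_values)
  grid$v_max <- purrr::pmap_dbl(grid, function(delta_rho, delta) {
    if (delta >= 36) return(NA_real_)
    m <- urchin_model(delta_rho = delta_rho, delta = delta, ...)
    vmax_over_orientations(m, stim, psi = seq(0, 359, by = psi_step))
  })
  structure(grid, class = c("urchin_sweep", class(grid)),
            family = family, phi_stim = phi_stim)
}

#' Randomized-acceptance-angle sweep
#'
#' Variant of [vmax_heatmap()] in which each photoreceptor draws its own
#' acceptance angle uniformly from `delta_rho + offsets` -- i.e. from
#' `[delta_rho + offsets[1], delta_rho + offsets[2]]` -- at every grid
#' point (seeded). A zero-width offset range reduces exactly to the fixed
#' sweep.
#'
#' @inheritParams vmax_heatmap
#' @param offsets length-2 numeric giving the half-range of the per-cell
#'   uniform distribution around each scanned `delta_rho`.
#' @param seed integer seed for the per-cell draws.
#' @return a tibble of class `urchin_sweep`.
#' @export
randomized_acceptance_sweep <- function(family, phi_stim,
                                        offsets = c(-5, 5),
                                        delta_rho_values =
                                          seq(15, 90, length.out = 16),
                                        delta_values =
                                          seq(5, 20, length.out = 16),
                                        psi_step = 1, seed = 1, ...) {
  if (length(offsets) != 2) abort("`offsets` must have length 2.")
  stim <- make_stimulus(family, phi_stim)
  grid <- tidyr::expand_grid(delta_rho = delta_rho_values,
                             delta = delta_values)
  grid$v_max <- purrr::pmap_dbl(
    cbind(grid, cell = seq_len(nrow(grid))),
    function(delta_rho, delta, cell) {
      if (delta >= 36) return(NA_real_)
      rng <- sort(delta_rho + offsets)
      rng <- pmin(pmax(rng, 1e-6), 180 - 1e-6)
      if (diff(rng) == 0) {
        m <- urchin_model(delta_rho = rng[1], delta = delta, ...)
      } else {
        m <- urchin_model(delta_rho = delta_rho, delta = delta,
                          delta_rho_range = rng,
                          seed = replicate_seed(seed, cell), ...)
      }
      vmax_over_orientations(m, stim, psi = seq(0, 359, by = psi_step))
    }
  )
  structure(grid, class = c("urchin_sweep", class(grid)),
            family = family, phi_stim = phi_stim, offsets = offsets,
            seed = seed)
}

#' Detection contours of a sweep
#'
#' Level sets of `v_max` over the (delta_rho, delta) plane, by default at
#' the detection threshold `theta_p` and at 4; the effective-acceptance
#' constraint line `delta_rho + 2 * delta = 60` is returned alongside for
#' overlay.
#'
#' @param sweep an `urchin_sweep`.
#' @param levels contour levels.
#' @return a list with `contours` (tibble: `level`, `piece`, `delta_rho`,
#'   `delta`; empty when no cell crosses a level) and `constraint_line`
#'   (tibble along `delta_rho + 2 * delta = 60`).
#' @export
detection_contours <- function(sweep, levels = c(5, 4)) {
  dr <- sort(unique(sweep$delta_rho))
  dd <- sort(unique(sweep$delta))
  z <- matrix(NA_real_, length(dr), length(dd))
  z[cbind(match(sweep$delta_rho, dr), match(sweep$delta, dd))] <- sweep$v_max
  if (any(!is.finite(z))) {
    # contourLines cannot handle NA; fill masked cells below all levels
    z[!is.finite(z)] <- min(c(z[is.finite(z)], 0)) - 1
  }
  cl <- if (diff(range(z)) == 0) list() else
    grDevices::contourLines(dr, dd, z, levels = levels)
  contours <- if (length(cl)) {
    purrr::imap_dfr(cl, function(pc, i) {
      tibble(level = pc$level, piece = i,
             delta_rho = pc$x, delta = pc$y)
    })
  } else {
    tibble(level = numeric(), piece = integer(),
           delta_rho = numeric(), delta = numeric())
  }
  dr_line <- seq(min(dr), max(dr), length.out = 100)
  constraint_line <- tibble(delta_rho = dr_line,
                            delta = (60 - dr_line) / 2)
  constraint_line <- constraint_line %>%
    filter(.data$delta >= min(dd), .data$delta <= max(dd))
  list(contours = contours, constraint_line = constraint_line)
}
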