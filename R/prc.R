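# Photoreceptor layer: five ambulacral arrays of screened photoreceptor
# groups with a rectified-cosine angular sensitivity kernel.

#' Rectified-cosine angular sensitivity
#'
#' Normalized angular sensitivity of a screened photoreceptor: a cosine
#' approximation to a truncated Gaussian tuning curve,
#' `f = max(0, (cos(phi - center) - a) / (1 - a))` with
#' `a = 2*cos(delta_rho/2) - 1`. The curve peaks at 1 when `phi == center`,
#' falls to 1/2 at `center +/- delta_rho/2` (so its full width at half
#' maximum is the acceptance angle `delta_rho`), and vanishes exactly for
#' angular distances beyond `acos(a)`.
#'
#' @param center direction of maximum sensitivity, degrees.
#' @param delta_rho acceptance angle in degrees, in `(0, 180)`.
#' @param phi angle(s) at which to evaluate, degrees; circular differences
#'   are used.
#' @return sensitivity values in `[0, 1]`.
#' @export
#' @examples
#' angular_sensitivity(0, 30, c(0, 15, 30))
angular_sensitivity <- function(center, delta_rho, phi) {
  a <- sensitivity_a(delta_rho)
  pmax(0, (cos_deg(ang_diff(phi, center)) - a) / (1 - a))
}

sensitivity_a <- function(delta_rho) {
  if (any(!is.finite(delta_rho)) || any(delta_rho <= 0) ||
      any(delta_rho >= 180)) {
    abort("`delta_rho` must lie in (0, 180) degrees.")
  }
  2 * cos_deg(delta_rho / 2) - 1
}

#' Build the photoreceptor-cell arrays
#'
#' Places `n_prc` photoreceptor groups uniformly on each of the five
#' ambulacra, ambulacrum `k` being centred at `72 * (k - 1)` degrees with the
#' groups spread over `[center - delta, center + delta]`. Each group's
#' direction of maximum sensitivity equals its angular location.
#'
#' @param n_prc groups per ambulacrum.
#' @param delta half-width of the location band, degrees; must be below 36 so
#'   neighbouring ambulacra do not overlap.
#' @param delta_rho acceptance angle in degrees; either a scalar shared by
#'   all cells or, if `delta_rho_range` is given, drawn per cell.
#' @param delta_rho_range optional length-2 numeric: per-cell acceptance
#'   angles are drawn uniformly from this range (a supplementary variant of
#'   the model); requires `seed` for reproducibility.
#' @param seed integer seed used only for the randomized acceptance angles.
#' @return a tibble of class `urchin_prc_array` with one row per group:
#'   `ambulacrum`, `cell`, `center_deg`, `delta_rho`; `delta` and `n_prc` are
#'   kept as attributes.
#' @export
#' @examples
#' prc <- build_prc_array()
#' dplyr::count(prc, ambulacrum)
build_prc_array <- function(n_prc = 100, delta = 15, delta_rho = 30,
                            delta_rho_range = NULL, seed = NULL) {
  stopifnot_scalar(n_prc, "n_prc", lo = 1)
  stopifnot_scalar(delta, "delta", lo = 0, hi = 36,
                   open_lo = TRUE, open_hi = TRUE)
  layout <- tidyr::expand_grid(ambulacrum = 1:5, cell = seq_len(n_prc)) %>%
    mutate(
      center_deg = wrap_angle(
        72 * (.data$ambulacrum - 1) +
          seq(-delta, delta, length.out = n_prc)[.data$cell]
      )
    )
  if (is.null(delta_rho_range)) {
    sensitivity_a(delta_rho) # validate range
    layout$delta_rho <- delta_rho
  } else {
    if (length(delta_rho_range) != 2 || any(delta_rho_range <= 0) ||
        any(delta_rho_range >= 180)) {
      abort("`delta_rho_range` must be two values inside (0, 180).")
    }
    if (!is.null(seed)) {
      withr_seed <- get0(".Random.seed", globalenv())
      set.seed(seed)
      on.exit(if (!is.null(withr_seed))
        assign(".Random.seed", withr_seed, envir = globalenv()))
    }
    layout$delta_rho <- runif(nrow(layout), min(delta_rho_range),
                              max(delta_rho_range))
  }
  structure(layout, class = c("urchin_prc_array", class(layout)),
            delta = delta, n_prc = n_prc)
}

prc_delta <- function(array) attr(array, "delta")

# Sensitivity matrix: rows = cells, columns = animal-frame grid angles.
prc_sensitivity_matrix <- function(array, grid) {
  a <- sensitivity_a(array$delta_rho)
  d <- outer(array$center_deg, grid, function(c, g) cos_deg(ang_diff(g, c)))
  f <- (d - a) / (1 - a) # recycles a down columns (row-wise constants)
  f[f < 0] <- 0
  f
}

#' Photoreceptor responses to a perceived intensity profile
#'
#' Each group integrates the animal-frame intensity profile weighted by its
#' angular sensitivity curve, normalized by the integral of the curve so
#' that a uniform profile of intensity `c` yields `c * r_max` (midpoint
#' quadrature on the profile grid).
#'
#' @param array an `urchin_prc_array`.
#' @param profile a perceived profile: tibble with `angle_deg` (uniform
#'   full-circle grid) and `intensity`, as from [perceived_profile()].
#' @param r_max maximal activity.
#' @return the `array` tibble with a `response` column appended.
#' @export
prc_response <- function(array, profile, r_max = 1) {
  grid <- profile$angle_deg
  f <- prc_sensitivity_matrix(array, grid)
  z <- base::rowSums(f)
  if (any(z <= 0)) abort("photoreceptor with all-zero sensitivity on grid")
  array$response <- r_max * as.vector(f %*% profile$intensity) / z
  array
}

#' Per-ambulacrum sensitivity envelope
#'
#' Pointwise maximum of the sensitivity curves of all photoreceptor groups
#' of one ambulacrum; its full width at half maximum is the effective
#' acceptance angle `delta_rho + 2 * delta`.
#'
#' @param array an `urchin_prc_array`.
#' @param ambulacrum which ambulacrum (1-5).
#' @param phi angles at which to evaluate (degrees).
#' @return numeric vector of envelope values.
#' @export
prc_envelope <- function(array, ambulacrum = 1, phi) {
  cells <- array[array$ambulacrum == ambulacrum, ]
  f <- prc_sensitivity_matrix(cells, phi)
  apply(f, 2, max)
}
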