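# Behavioral readout: static endpoints, step-by-step taxis trajectories,
# and cohort-level circular statistics.

#' Circular mean vector of bearings
#'
#' `r_f = (1/N) * sum_k (cos(alpha_k), sin(alpha_k))`; the mean resultant
#' length `|r_f|` is 1 for identical bearings and ~0 for uniform ones.
#'
#' @param bearings angles in degrees.
#' @return a one-row tibble: `r_x`, `r_y`, `length`, `direction_deg`, `n`.
#' @export
#' @examples
#' circular_mean(c(0, 0, 90))
circular_mean <- function(bearings) {
  if (!length(bearings)) abort("`bearings` must be non-empty.")
  rx <- mean(cos_deg(bearings))
  ry <- mean(sin_deg(bearings))
  tibble(r_x = rx, r_y = ry, length = sqrt(rx^2 + ry^2),
         direction_deg = atan2_deg(ry, rx), n = length(bearings))
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null of a uniform circular distribution against unimodal
#' concentration, with `z = n * Rbar^2` and the standard series
#' approximation of the p-value,
#' `p = exp(-z) * (1 + (2z - z^2)/(4n) - (24z - 132z^2 + 76z^3 - 9z^4)/(288 n^2))`,
#' clamped to `[0, 1]`.
#'
#' @param bearings angles in degrees, at least 4.
#' @return a one-row tibble: `n`, `r_bar`, `z`, `p_value`.
#' @export
rayleigh_test <- function(bearings) {
  n <- length(bearings)
  if (n < 4) abort("Rayleigh test requires at least 4 bearings.")
  rbar <- circular_mean(bearings)$length
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  tibble(n = n, r_bar = rbar, z = z, p_value = min(1, max(0, p)))
}

#' V test of circular uniformity against a specified direction
#'
#' One-sided test for concentration around a known expected direction
#' (here, the stimulus centre): `V = Rbar * cos(mean - expected)`,
#' `u = V * sqrt(2n)`, `p = 1 - Phi(u)`.
#'
#' @param bearings angles in degrees, at least 4.
#' @param expected_direction expected direction in degrees (default 0, the
#'   stimulus centre).
#' @return a one-row tibble: `n`, `v`, `u`, `p_value`.
#' @export
v_test <- function(bearings, expected_direction = 0) {
  n <- length(bearings)
  if (n < 4) abort("V test requires at least 4 bearings.")
  cm <- circular_mean(bearings)
  v <- cm$length * cos_deg(ang_diff(cm$direction_deg, expected_direction))
  u <- v * sqrt(2 * n)
  tibble(n = n, v = v, u = u, p_value = pnorm(u, lower.tail = FALSE))
}

# Wrapped-Gaussian draw (degrees); sd == 360 means uniform by convention.
rwrapped <- function(n, mean, sd) {
  if (sd >= 360) runif(n, 0, 360) else wrap_angle(rnorm(n, mean, sd))
}

#' Static final-bearing sampler
#'
#' Infers the final wall position from the population vector at the arena
#' centre: a uniform bearing if the vector length is at or below `theta_p`,
#' otherwise a wrapped Gaussian centred on the vector's arena-frame bearing
#' with s.d. `min(1 / (length - theta_p), 1)` radians.
#'
#' @param v_length population-vector length.
#' @param v_bearing arena-frame bearing of the vector, degrees.
#' @param theta_p detection threshold.
#' @param n number of draws.
#' @return bearings in degrees.
#' @export
static_endpoint <- function(v_length, v_bearing, theta_p = 5, n = 1) {
  if (v_length <= theta_p) {
    runif(n, 0, 360)
  } else {
    sd_deg <- rad2deg(min(1 / (v_length - theta_p), 1))
    rwrapped(n, v_bearing, sd_deg)
  }
}

#' Step-direction sampler of the dynamic taxis model
#'
#' The next heading is drawn from a two-component wrapped-Gaussian mixture:
#' with probability `q = 1 / (1 + exp(-q_steepness * (v - theta_p)))` around
#' the population-vector bearing with s.d.
#' `sigma_1 = max(10 / (v - theta_p), epsilon)` degrees (capped at 360,
#' which yields a uniform draw); otherwise around the previous heading with
#' fixed s.d. `sigma_2` (10 degrees by default).
#'
#' @param v_length population-vector length.
#' @param v_bearing arena-frame bearing of the vector, degrees.
#' @param phi_pre previous heading, degrees.
#' @param theta_p detection threshold.
#' @param sigma_2 persistence s.d., degrees.
#' @param q_steepness mixture-weight steepness.
#' @param epsilon floor for `sigma_1`, degrees.
#' @return one heading in degrees.
#' @export
step_direction <- function(v_length, v_bearing, phi_pre, theta_p = 5,
                           sigma_2 = 10, q_steepness = 10, epsilon = 1e-5) {
  q <- 1 / (1 + exp(-q_steepness * (v_length - theta_p)))
  if (runif(1) < q) {
    sigma_1 <- max(10 / (v_length - theta_p), epsilon)
    rwrapped(1, v_bearing, min(sigma_1, 360))
  } else {
    rwrapped(1, phi_pre, sigma_2)
  }
}

#' Simulate one step-by-step taxis trajectory
#'
#' The animal starts at the arena centre with fixed orientation `psi0` (it
#' does not rotate while moving). At each step the stimulus is re-perceived
#' from the current position, the network is solved to its steady state, a
#' heading is drawn by [step_direction()], and the animal advances by
#' `step_size` of the arena radius. The trajectory ends once the radial
#' distance reaches `stop_radius`.
#'
#' @param model an `urchin_model` (ideally with preferred directions
#'   attached).
#' @param stimulus an `urchin_stimulus`.
#' @param psi0 initial (and constant) orientation, degrees.
#' @param pref optional precomputed preferred-direction map.
#' @return a tibble of class `urchin_trajectory`: `step`, `x`, `y`,
#'   `heading_deg`, `v_length`; the final bearing (radial projection on the
#'   wall, degrees) is attribute `final_bearing`, and any non-converged
#'   steady states are counted in attribute `n_not_converged`.
#' @export
simulate_trajectory <- function(model, stimulus, psi0, pref = NULL) {
  map <- model_pref(model, pref)
  p <- model$params
  pos <- c(0, 0)
  phi_pre <- runif(1, 0, 360)
  steps <- list()
  n_bad <- 0L
  step <- 0L
  while (sqrt(sum(pos^2)) < p$stop_radius) {
    step <- step + 1L
    st <- solve_steady_state(model, stimulus,
                             animal_pose(pos[1], pos[2], psi0))
    if (!st$converged) n_bad <- n_bad + 1L
    pv <- population_vector(st$onr$rate, map, theta_p = p$theta_p)
    bearing <- wrap_angle(pv$direction_deg + psi0)
    heading <- step_direction(pv$length, bearing, phi_pre,
                              theta_p = p$theta_p, sigma_2 = p$sigma_2,
                              q_steepness = p$q_steepness,
                              epsilon = p$epsilon)
    pos <- pos + p$step_size * c(cos_deg(heading), sin_deg(heading))
    if (sqrt(sum(pos^2)) > 1) { # defensive: clip at the wall
      pos <- pos / sqrt(sum(pos^2)) * p$stop_radius
    }
    phi_pre <- heading
    steps[[step]] <- tibble(step = step, x = pos[1], y = pos[2],
                            heading_deg = heading, v_length = pv$length)
  }
  if (n_bad > 0) {
    warn(sprintf("%d steady-state solve(s) did not converge; last iterate used",
                 n_bad))
  }
  out <- bind_rows(steps)
  structure(out, class = c("urchin_trajectory", class(out)),
            psi0 = psi0,
            final_bearing = atan2_deg(pos[2], pos[1]),
            n_not_converged = n_bad)
}

# Deterministic per-replicate seed stream from one master seed.
replicate_seed <- function(master, r) {
  (as.numeric(master) + 1000003 * as.numeric(r)) %% 2147483647
}

#' Simulate a cohort of model sea urchins
#'
#' Runs `n_subjects` independent trials per replicate experiment, each with
#' a uniformly random initial orientation. In `"static"` mode the final
#' bearing is drawn by [static_endpoint()] from the centre-of-arena
#' population vector (precomputed on the 1-degree orientation grid); in
#' `"dynamic"` mode a full trajectory is simulated per subject. Each
#' replicate is summarised by the circular mean vector and Rayleigh/V-test
#' p-values (expected direction: the stimulus centre, 0 degrees).
#'
#' @param model an `urchin_model`.
#' @param stimulus an `urchin_stimulus`.
#' @param n_subjects subjects per replicate experiment.
#' @param n_replicates replicate experiments.
#' @param mode `"static"` or `"dynamic"`.
#' @param seed master seed; replicate streams are derived from it.
#' @param pref optional precomputed preferred-direction map.
#' @return an object of class `urchin_cohort`: list with `bearings`
#'   (tibble: `replicate`, `subject`, `psi0`, `bearing_deg`), `stats`
#'   (tibble per replicate: `r_f` length/direction and both p-values), and
#'   metadata. `glance()` gives the across-replicate means.
#' @export
#' @examples
#' m <- with_preferred_directions(urchin_model(n_prc = 20, n_onr = 60))
#' co <- run_cohort(m, make_stimulus("control"), n_subjects = 25,
#'                  n_replicates = 2, seed = 1)
#' generics::glance(co)
run_cohort <- function(model, stimulus, n_subjects = 100, n_replicates = 1,
                       mode = c("static", "dynamic"), seed = 1,
                       pref = NULL) {
  mode <- match.arg(mode)
  if (n_subjects < 1) abort("`n_subjects` must be at least 1.")
  map <- model_pref(model, pref)
  p <- model$params
  if (mode == "static") {
    pv <- population_vectors(model, stimulus, psi = 0:359, pref = map)
  }
  reps <- purrr::map(seq_len(n_replicates), function(r) {
    set.seed(replicate_seed(seed, r))
    if (mode == "static") {
      psi0 <- sample(0:359, n_subjects, replace = TRUE)
      bearing <- vapply(psi0, function(ps) {
        row <- pv[pv$psi == ps, ]
        static_endpoint(row$length, row$bearing_deg, theta_p = p$theta_p)
      }, numeric(1))
      tibble(replicate = r, subject = seq_len(n_subjects),
             psi0 = psi0, bearing_deg = bearing)
    } else {
      psi0 <- runif(n_subjects, 0, 360)
      bearing <- vapply(psi0, function(ps) {
        attr(simulate_trajectory(model, stimulus, ps, pref = map),
             "final_bearing")
      }, numeric(1))
      tibble(replicate = r, subject = seq_len(n_subjects),
             psi0 = psi0, bearing_deg = bearing)
    }
  })
  bearings <- bind_rows(reps)
  stats <- bearings %>%
    group_by(.data$replicate) %>%
    summarise(
      n = n(),
      r_f_length = circular_mean(.data$bearing_deg)$length,
      r_f_direction = circular_mean(.data$bearing_deg)$direction_deg,
      rayleigh_p = if (n() >= 4) rayleigh_test(.data$bearing_deg)$p_value
                   else NA_real_,
      v_test_p = if (n() >= 4) v_test(.data$bearing_deg, 0)$p_value
                 else NA_real_,
      .groups = "drop"
    )
  structure(
    list(bearings = bearings, stats = stats, mode = mode,
         family = attr(stimulus, "family"),
         phi_stim = attr(stimulus, "phi_stim"),
         n_subjects = n_subjects, n_replicates = n_replicates,
         seed = seed, theta_p = p$theta_p),
    class = "urchin_cohort"
  )
}

#' @export
print.urchin_cohort <- function(x, ...) {
  cat(sprintf(
    paste0("<urchin_cohort> %s %s: %d replicate(s) x %d subjects (%s mode)\n",
           "  mean |r_f| = %.3f, mean Rayleigh p = %.4g, mean V-test p = %.4g\n"),
    x$family, if (is.na(x$phi_stim)) "" else paste0(x$phi_stim, "deg"),
    x$n_replicates, x$n_subjects, x$mode,
    mean(x$stats$r_f_length), mean(x$stats$rayleigh_p),
    mean(x$stats$v_test_p)
  ))
  invisible(x)
}
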