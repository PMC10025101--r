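# Radial-nerve (RN) and oral-nerve-ring (ONR) rate layers, connectivity,
# and the synchronous fixed-point solver.
#
# Signal path: light excites photoreceptor groups (PRC), PRCs inhibit RN
# groups on the same ambulacrum (W_RP <= 0), RN groups excite one another
# laterally (W_RR >= 0), RN groups effectively inhibit excitatory ONR groups
# (W_OR <= 0; the inhibitory ONR interneurons are folded into these
# effective weights), and eONR groups excite their ring neighbours
# (W_OO >= 0). Light therefore *disinhibits* the eONR groups nearest the lit
# ambulacra.

#' Sigmoidal rate function
#'
#' `S(x) = 1 / (1 + exp(-2 * beta * (x - x_c)))`; strictly increasing with
#' `S(x_c) = 1/2`.
#'
#' @param x input (dimensionless, normalized by the maximal feedforward
#'   drive).
#' @param beta steepness (> 0).
#' @param x_c location parameter.
#' @return values in (0, 1).
#' @export
#' @examples
#' sigmoid(0, beta = 3, x_c = -0.6) # RN spontaneous rate ~ 0.973
sigmoid <- function(x, beta, x_c) {
  1 / (1 + exp(-2 * beta * (x - x_c)))
}

#' Model configuration and construction
#'
#' Builds the full decentralized-vision model: photoreceptor arrays,
#' connectivity weights, and solver settings. Defaults reproduce the
#' reference parameter table (100 PRC and RN groups per ambulacrum, 500 eONR
#' groups, acceptance angle 30 deg, location half-width 15 deg, lateral
#' strengths 0.25, RN sigmoid (beta 3, x_c -0.6), ONR sigmoid (beta 4.5,
#' x_c -0.45), detection threshold 5, step size 0.1).
#'
#' @param n_prc,n_rn PRC and RN groups per ambulacrum (must be equal: the
#'   PRC -> RN projection is index-aligned).
#' @param n_onr eONR groups on the ring.
#' @param delta_rho acceptance angle (deg).
#' @param delta half-width of PRC location band (deg), < 36.
#' @param delta_rho_range optional range for randomized per-cell acceptance
#'   angles; see [build_prc_array()].
#' @param r_max_prc,r_max_rn,r_max_onr maximal activities.
#' @param a_rr,a_oo lateral connection strengths.
#' @param beta_rn,x_c_rn,beta_onr,x_c_onr sigmoid parameters.
#' @param theta_p population-vector detection threshold.
#' @param step_size trajectory step as a fraction of the arena radius.
#' @param stop_radius radial distance at which a trajectory ends.
#' @param sigma_2 s.d. (deg) of the persistence component of the step
#'   direction mixture.
#' @param q_steepness steepness of the mixture weight `q(v)`.
#' @param epsilon floor (deg) for the stimulus-driven step s.d.
#' @param tol fixed-point convergence tolerance (max absolute rate change).
#' @param max_iter iteration cap of the solver.
#' @param grid_deg angular grid spacing (deg) for profiles.
#' @param rn_fanin_window PRC groups feeding one RN group (odd).
#' @param rn_lateral_window RN lateral neighbours per side.
#' @param onr_fanin_k nearest RN groups feeding one eONR group.
#' @param onr_lateral_window eONR lateral neighbours per side.
#' @param weight_scaling `"inverse_sqrt"` (default) scales each unit's
#'   afferent weights by the inverse square root of its fan-in;
#'   `"inverse_linear"` by the inverse fan-in. The input normalization makes
#'   the feedforward choice unobservable; only the lateral-to-feedforward
#'   ratio changes.
#' @param seed seed for the randomized acceptance-angle variant.
#' @return an object of class `urchin_model`.
#' @export
#' @examples
#' m <- urchin_model(n_prc = 20, n_onr = 60)
#' m
urchin_model <- function(n_prc = 100, n_rn = n_prc, n_onr = 500,
                         delta_rho = 30, delta = 15, delta_rho_range = NULL,
                         r_max_prc = 1, r_max_rn = 1, r_max_onr = 1,
                         a_rr = 0.25, a_oo = 0.25,
                         beta_rn = 3, x_c_rn = -0.6,
                         beta_onr = 4.5, x_c_onr = -0.45,
                         theta_p = 5, step_size = 0.1, stop_radius = 0.75,
                         sigma_2 = 10, q_steepness = 10, epsilon = 1e-5,
                         tol = 1e-5, max_iter = 600, grid_deg = 0.5,
                         rn_fanin_window = 3, rn_lateral_window = 1,
                         onr_fanin_k = 3, onr_lateral_window = 1,
                         weight_scaling = c("inverse_sqrt", "inverse_linear"),
                         seed = NULL) {
  weight_scaling <- match.arg(weight_scaling)
  if (n_rn != n_prc) {
    abort("`n_rn` must equal `n_prc` (index-aligned PRC -> RN projection).")
  }
  stopifnot_scalar(theta_p, "theta_p", lo = 0, open_lo = TRUE)
  stopifnot_scalar(step_size, "step_size", lo = 0, hi = 1, open_lo = TRUE)
  stopifnot_scalar(stop_radius, "stop_radius", lo = step_size, hi = 1,
                   open_hi = TRUE)
  stopifnot_scalar(beta_rn, "beta_rn", lo = 0, open_lo = TRUE)
  stopifnot_scalar(beta_onr, "beta_onr", lo = 0, open_lo = TRUE)

  prc <- build_prc_array(n_prc = n_prc, delta = delta, delta_rho = delta_rho,
                         delta_rho_range = delta_rho_range, seed = seed)
  onr_pos <- seq(0, 360, length.out = n_onr + 1)[seq_len(n_onr)]
  params <- list(
    n_prc = n_prc, n_rn = n_rn, n_onr = n_onr,
    delta_rho = delta_rho, delta = delta,
    delta_rho_range = delta_rho_range,
    r_max_prc = r_max_prc, r_max_rn = r_max_rn, r_max_onr = r_max_onr,
    a_rr = a_rr, a_oo = a_oo,
    beta_rn = beta_rn, x_c_rn = x_c_rn,
    beta_onr = beta_onr, x_c_onr = x_c_onr,
    theta_p = theta_p, step_size = step_size, stop_radius = stop_radius,
    sigma_2 = sigma_2, q_steepness = q_steepness, epsilon = epsilon,
    tol = tol, max_iter = max_iter, grid_deg = grid_deg,
    rn_fanin_window = rn_fanin_window,
    rn_lateral_window = rn_lateral_window,
    onr_fanin_k = onr_fanin_k, onr_lateral_window = onr_lateral_window,
    weight_scaling = weight_scaling, seed = seed
  )
  grid <- seq(0, 360 - grid_deg, by = grid_deg)
  model <- structure(
    list(
      params = params,
      prc = prc,
      rn_pos = prc$center_deg,       # RN groups sit under their PRC groups
      onr_pos = onr_pos,
      grid = grid,
      sens = prc_sensitivity_matrix(prc, grid),
      weights = build_weights(
        list(n_prc = n_prc, n_onr = n_onr,
             a_rr = a_rr, a_oo = a_oo,
             rn_fanin_window = rn_fanin_window,
             rn_lateral_window = rn_lateral_window,
             onr_fanin_k = onr_fanin_k,
             onr_lateral_window = onr_lateral_window,
             weight_scaling = weight_scaling,
             r_max_prc = r_max_prc, r_max_rn = r_max_rn),
        prc, n_onr
      ),
      pref = NULL
    ),
    class = "urchin_model"
  )
  model$sens_rowsum <- base::rowSums(model$sens)
  model
}

#' @export
print.urchin_model <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    paste0(
      "<urchin_model> 5 x %d PRC/RN groups, %d eONR groups\n",
      "  delta_rho=%s deg, delta=%g deg, a_RR=%g, a_OO=%g, theta_p=%g\n",
      "  RN sigmoid (beta=%g, x_c=%g); ONR sigmoid (beta=%g, x_c=%g)\n",
      "  preferred directions: %s\n"
    ),
    p$n_prc, p$n_onr,
    if (is.null(p$delta_rho_range)) format(p$delta_rho) else
      sprintf("U[%g, %g]", p$delta_rho_range[1], p$delta_rho_range[2]),
    p$delta, p$a_rr, p$a_oo, p$theta_p,
    p$beta_rn, p$x_c_rn, p$beta_onr, p$x_c_onr,
    if (is.null(x$pref)) "not yet computed" else "attached"
  ))
  invisible(x)
}

scale_factor <- function(fanin, scaling) {
  if (scaling == "inverse_sqrt") 1 / sqrt(fanin) else 1 / fanin
}

#' Build the connectivity weights
#'
#' Constructs the four weight matrices as sparse matrices:
#' `W_RP` (PRC -> RN, inhibitory, index-aligned window on the same
#' ambulacrum, truncated at ambulacrum edges), `W_RR` (RN lateral
#' excitation, adjacent groups within the same ambulacrum), `W_OR`
#' (effective RN -> eONR inhibition, the `onr_fanin_k` angularly nearest RN
#' groups on the nearest ambulacrum), and `W_OO` (eONR ring lateral
#' excitation). Each unit's afferent weight magnitude is
#' `scale(fan-in)` (times `a_RR`/`a_OO` for lateral weights).
#'
#' @param config list with counts, lateral strengths, window sizes,
#'   `weight_scaling`, and maximal rates (see [urchin_model()]).
#' @param prc an `urchin_prc_array`.
#' @param n_onr number of eONR groups.
#' @return list with sparse matrices `W_rp`, `W_rr`, `W_or`, `W_oo` and the
#'   input normalizers `den_rn`, `den_onr` (the magnitude of each unit's
#'   maximal feedforward drive).
#' @export
build_weights <- function(config, prc, n_onr) {
  n <- config$n_prc
  n_rn_total <- 5L * n
  scaling <- config$weight_scaling

  # --- W_RP: PRC -> RN, index-aligned window within each ambulacrum.
  half <- (config$rn_fanin_window - 1) / 2
  if (half != floor(half)) abort("`rn_fanin_window` must be odd.")
  rp <- purrr::map_dfr(1:5, function(k) {
    purrr::map_dfr(seq_len(n), function(i) {
      j <- max(1, i - half):min(n, i + half)
      tibble(i = (k - 1) * n + i, j = (k - 1) * n + j)
    })
  })
  rp <- rp %>% group_by(.data$i) %>%
    mutate(w = -scale_factor(n(), scaling)) %>% ungroup()
  W_rp <- sparseMatrix(i = rp$i, j = rp$j, x = rp$w,
                       dims = c(n_rn_total, n_rn_total))

  # --- W_RR: lateral excitation among adjacent RN groups, no self link,
  # not crossing ambulacrum boundaries.
  lw <- config$rn_lateral_window
  rr <- purrr::map_dfr(1:5, function(k) {
    purrr::map_dfr(seq_len(n), function(i) {
      j <- setdiff(max(1, i - lw):min(n, i + lw), i)
      if (!length(j)) return(NULL)
      tibble(i = (k - 1) * n + i, j = (k - 1) * n + j)
    })
  })
  rr <- rr %>% group_by(.data$i) %>%
    mutate(w = config$a_rr * scale_factor(n(), scaling)) %>% ungroup()
  W_rr <- sparseMatrix(i = rr$i, j = rr$j, x = rr$w,
                       dims = c(n_rn_total, n_rn_total))

  # --- W_OR: each eONR group receives the k_n angularly nearest RN groups
  # of its nearest ambulacrum (effective inhibition via iONR interneurons).
  onr_pos <- seq(0, 360, length.out = n_onr + 1)[seq_len(n_onr)]
  k_n <- config$onr_fanin_k
  # deterministic, exactly five-fold-symmetric assignment: the ambulacrum is
  # chosen by position band (midpoints go to the clockwise neighbour), and
  # RN distances are evaluated in ambulacrum-relative coordinates rounded to
  # 1e-6 deg so ties resolve identically on every ambulacrum.
  rn_offsets <- seq(-prc_delta(prc), prc_delta(prc), length.out = n)
  or <- purrr::map_dfr(seq_len(n_onr), function(i) {
    amb <- (floor((onr_pos[i] + 36) / 72 + 1e-9) %% 5) + 1
    rel <- ang_diff(onr_pos[i], 72 * (amb - 1))
    d <- round(abs(rel - rn_offsets), 6)
    j <- (amb - 1) * n + order(d, seq_len(n))[seq_len(min(k_n, n))]
    tibble(i = i, j = j)
  })
  or <- or %>% group_by(.data$i) %>%
    mutate(w = -scale_factor(n(), scaling)) %>% ungroup()
  W_or <- sparseMatrix(i = or$i, j = or$j, x = or$w,
                       dims = c(n_onr, n_rn_total))

  # --- W_OO: ring lateral excitation among adjacent eONR groups.
  ow <- config$onr_lateral_window
  oo <- purrr::map_dfr(seq_len(n_onr), function(i) {
    j <- ((i - 1 + c(-(ow:1), 1:ow)) %% n_onr) + 1
    tibble(i = i, j = unique(j[j != i]))
  })
  oo <- oo %>% group_by(.data$i) %>%
    mutate(w = config$a_oo * scale_factor(n(), scaling)) %>% ungroup()
  W_oo <- sparseMatrix(i = oo$i, j = oo$j, x = oo$w,
                       dims = c(n_onr, n_onr))

  den_rn <- as.vector(Matrix::rowSums(abs(W_rp))) * config$r_max_prc
  den_onr <- as.vector(Matrix::rowSums(abs(W_or))) * config$r_max_rn
  if (any(den_rn <= 0) || any(den_onr <= 0)) {
    abort("empty feedforward fan-in for some unit")
  }
  list(W_rp = W_rp, W_rr = W_rr, W_or = W_or, W_oo = W_oo,
       den_rn = den_rn, den_onr = den_onr)
}

#' One synchronous radial-nerve update
#'
#' `r_RN <- r_max * S((W_RP r_PRC + W_RR r_RN) / |W_RP(i)| r_max_PRC)`.
#'
#' @param r_prc,r_rn current activity vectors (or matrices, one column per
#'   independent case).
#' @param model an `urchin_model`.
#' @return updated RN activities, same shape as `r_rn`.
#' @export
rn_update <- function(r_prc, r_rn, model) {
  p <- model$params; w <- model$weights
  x <- (w$W_rp %*% r_prc + w$W_rr %*% r_rn) / w$den_rn
  p$r_max_rn * sigmoid(as.matrix(x), p$beta_rn, p$x_c_rn)
}

#' One synchronous oral-nerve-ring update
#'
#' `r_ONR <- r_max * S((W_OR r_RN + W_OO r_ONR) / |W_OR(i)| r_max_RN)`.
#'
#' @param r_rn,r_onr current activity vectors (or matrices).
#' @param model an `urchin_model`.
#' @return updated eONR activities.
#' @export
onr_update <- function(r_rn, r_onr, model) {
  p <- model$params; w <- model$weights
  x <- (w$W_or %*% r_rn + w$W_oo %*% r_onr) / w$den_onr
  p$r_max_onr * sigmoid(as.matrix(x), p$beta_onr, p$x_c_onr)
}

# Core batched solver. `prc_mat`: matrix (5*n_prc) x m of photoreceptor
# activities, one column per independent case (held fixed). Synchronous
# updates from a common initialization until the max per-unit change of a
# column first falls below tol; converged columns are frozen.
solve_fixed_point <- function(model, prc_mat, init = c("zero", "rmax")) {
  init <- match.arg(init)
  p <- model$params
  m <- ncol(prc_mat)
  n_rn <- nrow(prc_mat)
  r_rn <- matrix(if (init == "zero") 0 else p$r_max_rn, n_rn, m)
  r_onr <- matrix(if (init == "zero") 0 else p$r_max_onr, p$n_onr, m)
  iterations <- rep(NA_integer_, m)
  active <- rep(TRUE, m)
  for (it in seq_len(p$max_iter)) {
    idx <- which(active)
    new_rn <- rn_update(prc_mat[, idx, drop = FALSE],
                        r_rn[, idx, drop = FALSE], model)
    new_onr <- onr_update(r_rn[, idx, drop = FALSE],
                          r_onr[, idx, drop = FALSE], model)
    resid <- pmax(
      apply(abs(new_rn - r_rn[, idx, drop = FALSE]), 2, max),
      apply(abs(new_onr - r_onr[, idx, drop = FALSE]), 2, max)
    )
    r_rn[, idx] <- new_rn
    r_onr[, idx] <- new_onr
    done <- resid < p$tol
    iterations[idx[done]] <- it
    active[idx[done]] <- FALSE
    if (!any(active)) break
  }
  converged <- !active
  iterations[!converged] <- p$max_iter
  list(r_rn = r_rn, r_onr = r_onr,
       iterations = iterations, converged = converged)
}

# PRC activity matrix for a set of center-of-arena orientations (psi):
# perceived profile is the wall profile sampled at grid + psi.
prc_matrix_for_orientations <- function(model, stimulus, psi) {
  ink_fun <- attr(stimulus, "ink_fun")
  if (is.null(ink_fun)) abort("`stimulus` must be an `urchin_stimulus`.")
  X <- vapply(psi, function(ps) 1 - ink_fun(model$grid + ps),
              numeric(length(model$grid)))
  p <- model$params
  p$r_max_prc * (model$sens %*% X) / model$sens_rowsum
}

#' Solve the network to its steady state
#'
#' Computes the photoreceptor response to the stimulus as perceived from the
#' given pose (held fixed), then iterates the RN and eONR layers
#' synchronously from zero activity until the maximum per-unit rate change
#' falls below `tol` (default 1e-5) or `max_iter` (default 600) iterations.
#' Non-convergence is flagged, not raised.
#'
#' @param model an `urchin_model`.
#' @param stimulus an `urchin_stimulus`.
#' @param pose an [animal_pose()]; default: arena centre, `psi = 0`.
#' @param init initialization, `"zero"` (default) or `"rmax"`.
#' @return an object of class `urchin_state`: list with tibbles `prc`, `rn`
#'   (columns `ambulacrum`, `cell`, `angle_deg`, `rate`), `onr` (`cell`,
#'   `angle_deg`, `rate`), plus `iterations`, `converged`, `residual_tol`.
#' @export
#' @examples
#' m <- urchin_model(n_prc = 20, n_onr = 60)
#' st <- solve_steady_state(m, make_stimulus("control"))
#' st$converged
solve_steady_state <- function(model, stimulus, pose = animal_pose(),
                               init = c("zero", "rmax")) {
  if (!inherits(pose, "animal_pose")) {
    pose <- animal_pose(pose$x %||% 0, pose$y %||% 0, pose$psi %||% 0)
  }
  p <- model$params
  if (pose$x == 0 && pose$y == 0) {
    prc_mat <- prc_matrix_for_orientations(model, stimulus, pose$psi)
  } else {
    prof <- perceived_profile(stimulus, pose,
                              geometry = arena_geometry(p$grid_deg))
    prc_mat <- matrix(
      p$r_max_prc * as.vector(model$sens %*% prof$intensity) /
        model$sens_rowsum,
      ncol = 1
    )
  }
  sol <- solve_fixed_point(model, as.matrix(prc_mat), init = init)
  amb <- model$prc$ambulacrum
  structure(
    list(
      prc = tibble(ambulacrum = amb, cell = model$prc$cell,
                   angle_deg = model$prc$center_deg,
                   rate = as.vector(prc_mat)),
      rn = tibble(ambulacrum = amb, cell = model$prc$cell,
                  angle_deg = model$rn_pos, rate = as.vector(sol$r_rn)),
      onr = tibble(cell = seq_len(p$n_onr), angle_deg = model$onr_pos,
                   rate = as.vector(sol$r_onr)),
      iterations = sol$iterations[1],
      converged = sol$converged[1],
      residual_tol = p$tol,
      pose = pose
    ),
    class = "urchin_state"
  )
}

#' @export
print.urchin_state <- function(x, ...) {
  cat(sprintf(
    "<urchin_state> %s in %d iteration(s); mean rates PRC %.3f, RN %.3f, eONR %.3f\n",
    if (x$converged) "converged" else "NOT converged",
    x$iterations, mean(x$prc$rate), mean(x$rn$rate), mean(x$onr$rate)
  ))
  invisible(x)
}
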