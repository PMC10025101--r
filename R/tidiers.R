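# broom-style tidiers for the package's objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a model: one row per parameter
#'
#' @param x an `urchin_model`.
#' @param ... unused.
#' @return a tibble with `parameter` and `value` (list column for
#'   non-scalar entries).
#' @export
tidy.urchin_model <- function(x, ...) {
  p <- x$params
  tibble(
    parameter = names(p),
    value = vapply(p, function(v) {
      if (is.null(v)) NA_character_ else paste(format(v), collapse = ", ")
    }, character(1))
  )
}

#' Model summary at a glance
#'
#' @param x an `urchin_model`.
#' @param ... unused.
#' @return a one-row tibble with layer sizes and the key optics/readout
#'   parameters.
#' @export
glance.urchin_model <- function(x, ...) {
  p <- x$params
  tibble(
    n_prc_total = 5 * p$n_prc, n_rn_total = 5 * p$n_rn, n_onr = p$n_onr,
    delta_rho = if (is.null(p$delta_rho_range)) p$delta_rho else NA_real_,
    delta = p$delta, effective_acceptance =
      if (is.null(p$delta_rho_range)) p$delta_rho + 2 * p$delta else NA_real_,
    theta_p = p$theta_p,
    has_pref_map = !is.null(x$pref)
  )
}

#' Tidy a steady state: long activity table
#'
#' @param x an `urchin_state`.
#' @param ... unused.
#' @return a tibble with `layer`, `ambulacrum` (NA for the ring),
#'   `cell`, `angle_deg`, `rate`.
#' @export
tidy.urchin_state <- function(x, ...) {
  bind_rows(
    x$prc %>% mutate(layer = "PRC"),
    x$rn %>% mutate(layer = "RN"),
    x$onr %>% mutate(layer = "eONR", ambulacrum = NA_integer_)
  ) %>%
    select("layer", "ambulacrum", "cell", "angle_deg", "rate")
}

#' Steady-state summary at a glance
#'
#' @param x an `urchin_state`.
#' @param ... unused.
#' @return a one-row tibble: convergence flag, iterations, mean rate per
#'   layer.
#' @export
glance.urchin_state <- function(x, ...) {
  tibble(
    converged = x$converged, iterations = x$iterations,
    mean_prc = mean(x$prc$rate), mean_rn = mean(x$rn$rate),
    mean_onr = mean(x$onr$rate)
  )
}

#' Tidy a cohort: per-replicate statistics
#'
#' @param x an `urchin_cohort`.
#' @param ... unused.
#' @return the per-replicate stats tibble.
#' @export
tidy.urchin_cohort <- function(x, ...) x$stats

#' Cohort summary at a glance
#'
#' @param x an `urchin_cohort`.
#' @param ... unused.
#' @return a one-row tibble with across-replicate mean resultant length and
#'   mean Rayleigh/V-test p-values.
#' @export
glance.urchin_cohort <- function(x, ...) {
  tibble(
    family = x$family, phi_stim = x$phi_stim, mode = x$mode,
    n_subjects = x$n_subjects, n_replicates = x$n_replicates,
    mean_r_f_length = mean(x$stats$r_f_length),
    mean_rayleigh_p = mean(x$stats$rayleigh_p),
    mean_v_test_p = mean(x$stats$v_test_p)
  )
}
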