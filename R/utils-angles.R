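#' @keywords internal
"_PACKAGE"

#' @import tibble
#' @importFrom dplyr %>% mutate filter arrange group_by ungroup summarise
#'   bind_rows left_join select pull n across row_number
#' @importFrom rlang abort warn %||% .data
#' @importFrom Matrix sparseMatrix
#' @importFrom stats rnorm runif pnorm optimize uniroot sd quantile
NULL

# Degree-based trigonometry; all public angles are degrees.
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

cos_deg <- function(x) cos(deg2rad(x))
sin_deg <- function(x) sin(deg2rad(x))

#' Wrap angles into [0, 360)
#' @param x numeric vector of angles in degrees.
#' @return angles in degrees wrapped to `[0, 360)`.
#' @export
wrap_angle <- function(x) x %% 360

# Signed circular difference wrapped to (-180, 180].
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# atan2 in degrees, wrapped to [0, 360)
atan2_deg <- function(y, x) wrap_angle(rad2deg(atan2(y, x)))

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf,
                             open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar.", name))
  }
  ok_lo <- if (open_lo) x > lo else x >= lo
  ok_hi <- if (open_hi) x < hi else x <= hi
  if (!ok_lo || !ok_hi) {
    abort(sprintf(
      "`%s` must be in %s%g, %g%s (got %g).",
      name, if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]", x
    ))
  }
  invisible(x)
}
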