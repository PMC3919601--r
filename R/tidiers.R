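#' Tidy a binding fit
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble(term = c("Kd", "Bmax"),
         estimate = c(x$Kd, x$Bmax),
         std.error = c(x$se_Kd, x$se_Bmax))
}

#' @rdname tidy.binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n_points, mode = x$mode,
         converged = x$converged, boundary = any(x$boundary))
}

#' Tidy a kinetic fit
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble(term = c("kapp", "amplitude"),
         estimate = c(x$kapp, x$amplitude),
         std.error = c(x$se_kapp, x$se_amplitude))
}

#' @rdname tidy.kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n_points, converged = x$converged)
}

#' Tidy a Scatchard regression
#' @param x A `scatchard_result`.
#' @param ... Unused.
#' @return One row per derived quantity.
#' @export
tidy.scatchard_result <- function(x, ...) {
  tibble(term = c("slope", "Kd", "x_intercept"),
         estimate = c(x$slope, x$Kd, x$x_intercept))
}

#' @rdname tidy.scatchard_result
#' @export
glance.scatchard_result <- function(x, ...) {
  tibble(r.squared = x$r_squared, n = x$n_points)
}

#' Tidy a rotation score
#' @param x A `rotation_score`.
#' @param ... Unused.
#' @return Per-base clipped continuum positions.
#' @export
tidy.rotation_score <- function(x, ...) {
  x$per_base
}

#' @rdname tidy.rotation_score
#' @export
glance.rotation_score <- function(x, ...) {
  tibble(sample = x$sample_name, score = x$score,
         n_informative = x$n_informative,
         n_missing = length(x$missing),
         b3_pass = if (is.null(x$b3_check)) NA else x$b3_check$pass,
         classification = classify_rotation(x))
}

#' Tidy a fidelity result
#' @param x A `fidelity_result`.
#' @param ... Unused.
#' @return Per-replicate recoding percentages.
#' @export
tidy.fidelity_result <- function(x, ...) {
  tibble(replicate = seq_along(x$replicate_percent),
         percent = x$replicate_percent)
}

#' @rdname tidy.fidelity_result
#' @export
glance.fidelity_result <- function(x, ...) {
  tibble(percent = x$percent, sem = x$sem, n = x$n, method = x$method)
}

#' Tidy a competition result
#' @param x A `competition_result`.
#' @param ... Unused.
#' @return One-row summary of the trend test and half-effect dose.
#' @export
tidy.competition_result <- function(x, ...) {
  tibble(trend = x$trend, rho = x$rho, p.value = x$p_value, ec50 = x$ec50)
}
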