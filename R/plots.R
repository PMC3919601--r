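#' Plot a normalized reactivity trace
#'
#' Bar plot of reactivity against position with the discretization
#' thresholds (median, mean, mean + 1 SD, mean + 2 SD) overlaid.
#'
#' @param object A `normalized_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.normalized_trace <- function(object, ...) {
  st <- trace_statistics(object)
  thresholds <- tibble(
    name = factor(c("median", "mean", "mean + 1 SD", "mean + 2 SD"),
                  levels = c("median", "mean", "mean + 1 SD", "mean + 2 SD")),
    value = c(st$median, st$mean, st$mean + st$sd, st$mean + 2 * st$sd)
  )
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data$reactivity)) +
    ggplot2::geom_col(width = 1, fill = "grey35") +
    ggplot2::geom_hline(data = thresholds,
                        ggplot2::aes(yintercept = .data$value,
                                     colour = .data$name),
                        linetype = "dashed") +
    ggplot2::labs(x = "rRNA position", y = "Normalized reactivity",
                  colour = "Threshold",
                  title = object$region_id[1]) +
    ggplot2::theme_minimal()
}

#' Plot a difference map
#'
#' Per-position reactivity differences colored by the signed SD bin used
#' for structure-diagram coloring.
#'
#' @param object A `difference_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.difference_map <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data$delta,
                               fill = factor(.data$bin, levels = -4:4))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_brewer(palette = "RdBu", direction = -1,
                               drop = FALSE, name = "SD bin") +
    ggplot2::labs(x = "rRNA position",
                  y = "Reactivity difference (A - B)") +
    ggplot2::theme_minimal()
}

#' Plot a binding fit
#'
#' Observed signal over the dose series with the fitted ligand-depletion
#' curve.
#'
#' @param object A `binding_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.binding_fit <- function(object, ...) {
  grid <- tibble(dose = exp(seq(log(min(object$data$dose)),
                                log(max(object$data$dose)),
                                length.out = 200)))
  grid$y <- bound_closed_form(grid$dose, object$Kd, object$Bmax)
  if (object$mode == "unbound_measured") grid$y <- grid$dose - grid$y
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dose, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Total ligand (pmol)",
                  y = if (object$mode == "bound_measured") {
                    "Bound (pmol)"
                  } else {
                    "Unbound signal (pmol)"
                  },
                  title = sprintf("Kd = %.3g pmol, Bmax = %.3g pmol",
                                  object$Kd, object$Bmax)) +
    ggplot2::theme_minimal()
}

#' Plot a single-turnover kinetic fit
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  grid <- tibble(t = seq(0, max(object$data$t), length.out = 200))
  grid$y <- object$amplitude * (1 - exp(-object$kapp * grid$t)) +
    (object$offset %||% 0)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "Time (min)", y = "Product",
                  title = sprintf("kapp = %.3g /min", object$kapp)) +
    ggplot2::theme_minimal()
}

#' Plot rotation scores of a cohort
#'
#' Dot plot of rotation scores on the non-rotated (0) to rotated (1)
#' continuum, in the supplied order.
#'
#' @param scores Tibble from [simulate_cohort()] (columns `state`,
#'   `score`).
#' @return A ggplot.
#' @export
plot_rotation_continuum <- function(scores) {
  df <- dplyr::mutate(scores,
                      state = factor(.data$state, levels = .data$state))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$state)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_vline(xintercept = c(0, 1), linetype = "dotted") +
    ggplot2::xlim(-0.02, 1.02) +
    ggplot2::labs(x = "Rotation score (0 = non-rotated, 1 = rotated)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
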