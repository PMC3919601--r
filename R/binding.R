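#' Single-site equilibrium binding with ligand depletion
#'
#' In filter-binding assays the bound ligand is a non-negligible fraction of
#' total, so the free-ligand approximation fails and the equilibrium must be
#' solved exactly.  With total binding capacity `Bmax`, total ligand `L` and
#' dissociation constant `Kd` (all in pmol per fixed reaction volume) the
#' bound amount is the smaller root of `(Bmax - B)(L - B)/B = Kd`:
#' `B = (S - sqrt(S^2 - 4 Bmax L)) / 2` with `S = Bmax + L + Kd`.  The
#' rationalized form `2 Bmax L / (S + sqrt(S^2 - 4 Bmax L))` is used to
#' avoid cancellation in the stoichiometric (`Kd -> 0`) limit.
#'
#' @param dose Total ligand per reaction (pmol); vectorized.  Zero allowed.
#' @param Kd Dissociation constant (pmol), > 0.
#' @param Bmax Maximal binding (pmol), > 0.
#' @return Bound ligand (pmol), satisfying `0 <= B <= min(Bmax, dose)`.
#' @examples
#' bound_closed_form(10, Kd = 2, Bmax = 5) # ~3.783
#' @export
bound_closed_form <- function(dose, Kd, Bmax) {
  if (any(dose < 0)) abort("dose must be non-negative")
  if (Kd <= 0 || Bmax <= 0) abort("Kd and Bmax must be positive")
  s <- Bmax + dose + Kd
  disc <- pmax(s^2 - 4 * Bmax * dose, 0)
  2 * Bmax * dose / (s + sqrt(disc))
}

#' Fit the ligand-depletion binding model to a dose series
#'
#' Least-squares fit of the single-site ligand-depletion curve to a
#' background-subtracted dose series, in bound-measured mode (signal is the
#' bound amount) or unbound-measured mode (signal is total minus bound,
#' e.g. unbound factor recovered in the supernatant).  Replicates are fitted
#' jointly.  Because depletion likelihoods are shallow at low doses the fit
#' is multistarted: `Kd` from the dose-range minimum, geometric mean and
#' maximum crossed with `Bmax` at 1x and 1.5x the largest observed bound
#' value; the best residual sum of squares wins.
#'
#' @param assay Tibble with columns `dose_pmol`, `replicate`, `signal` and
#'   optionally `background` (subtracted before fitting); at least 4
#'   distinct doses.
#' @param mode `"bound_measured"` or `"unbound_measured"`; defaults to the
#'   assay's `mode` attribute when present.
#' @return An object of class `binding_fit`: `Kd`, `Bmax`, their standard
#'   errors, `rss`, `n_points`, `converged` and `boundary` flags, the data
#'   and mode.
#' @export
fit_binding <- function(assay, mode = NULL) {
  mode <- mode %||% attr(assay, "mode") %||% "bound_measured"
  mode <- match.arg(mode, c("bound_measured", "unbound_measured"))
  if (!all(c("dose_pmol", "signal") %in% names(assay))) {
    abort("assay needs columns dose_pmol and signal")
  }
  if (length(unique(assay$dose_pmol)) < 4) {
    abort("at least 4 distinct doses are required")
  }
  signal <- assay$signal -
    (if ("background" %in% names(assay)) assay$background else 0)
  dose <- assay$dose_pmol
  bound_obs <- if (mode == "bound_measured") signal else dose - signal
  df <- tibble(dose = dose, y = signal)

  model <- if (mode == "bound_measured") {
    y ~ bound_closed_form(dose, Kd, Bmax)
  } else {
    y ~ dose - bound_closed_form(dose, Kd, Bmax)
  }
  bmax_top <- max(max(bound_obs), 1e-6)
  starts <- tidyr::expand_grid(
    Kd = c(min(dose), exp(mean(log(dose))), max(dose)),
    Bmax = bmax_top * c(1, 1.5)
  )
  lower <- c(Kd = 1e-9, Bmax = 1e-9)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(model, data = df,
                        start = list(Kd = starts$Kd[i],
                                     Bmax = starts$Bmax[i]),
                        lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    abort("binding fit failed to converge from every start")
  }
  fit <- best$fit
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Kd = NA_real_, Bmax = NA_real_))
  boundary <- est <= 2 * lower
  converged <- fit$convInfo$isConv %||% TRUE
  if (!converged) warn("binding fit did not report convergence")
  if (any(boundary)) {
    warn(paste0("parameter(s) pinned at the lower boundary: ",
                paste(names(est)[boundary], collapse = ", ")))
  }
  structure(list(Kd = unname(est["Kd"]), Bmax = unname(est["Bmax"]),
                 se_Kd = unname(se["Kd"]), se_Bmax = unname(se["Bmax"]),
                 rss = best$rss, n_points = nrow(df), mode = mode,
                 converged = converged, boundary = boundary,
                 data = df, fit = fit),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Single-site ligand-depletion fit (%s, %d points)\n",
              x$mode, x$n_points))
  cat(sprintf("  Kd   = %.4g pmol (SE %.3g)\n", x$Kd, x$se_Kd))
  cat(sprintf("  Bmax = %.4g pmol (SE %.3g)\n", x$Bmax, x$se_Bmax))
  cat(sprintf("  RSS  = %.4g\n", x$rss))
  invisible(x)
}

#' Kd fold-change between two binding fits
#'
#' @param fit_mut,fit_wt Converged [fit_binding()] results.
#' @return Tibble with `ratio` (`Kd_mut / Kd_wt`) and `se` by first-order
#'   error propagation.
#' @export
kd_fold_change <- function(fit_mut, fit_wt) {
  kds <- c(fit_mut$Kd, fit_wt$Kd)
  if (any(!is.finite(kds)) || any(kds <= 0)) {
    abort("both fits must have positive finite Kd")
  }
  ratio <- fit_mut$Kd / fit_wt$Kd
  rel <- sqrt((fit_mut$se_Kd / fit_mut$Kd)^2 + (fit_wt$se_Kd / fit_wt$Kd)^2)
  tibble(ratio = ratio, se = ratio * rel)
}

#' Scatchard analysis of a binding dose series
#'
#' Ordinary least-squares regression of bound/free against bound.  For a
#' single site the plot is linear with slope `-1/Kd` and x-intercept
#' `Bmax`; curvature (low r-squared) indicates multiple site classes.
#' Saturated points with non-positive free ligand are excluded with a
#' warning.
#'
#' @param assay Tibble with `dose_pmol` and `signal` columns (and optional
#'   `background`).
#' @param mode `"bound_measured"` or `"unbound_measured"`, as in
#'   [fit_binding()]; defaults to the assay's `mode` attribute.
#' @return An object of class `scatchard_result`: `slope`, `Kd`
#'   (`-1/slope`), `x_intercept` (`Bmax`), `r_squared`, `n_points`.
#' @export
scatchard <- function(assay, mode = NULL) {
  mode <- mode %||% attr(assay, "mode") %||% "bound_measured"
  mode <- match.arg(mode, c("bound_measured", "unbound_measured"))
  signal <- assay$signal -
    (if ("background" %in% names(assay)) assay$background else 0)
  bound <- if (mode == "bound_measured") signal else assay$dose_pmol - signal
  free <- assay$dose_pmol - bound
  bad <- free <= 0
  if (any(bad)) {
    warn(sprintf("excluding %d saturated point(s) with free ligand <= 0",
                 sum(bad)))
    bound <- bound[!bad]
    free <- free[!bad]
  }
  if (length(bound) < 3) abort("too few unsaturated points for regression")
  reg <- lm(I(bound / free) ~ bound)
  slope <- unname(coef(reg)[2])
  intercept <- unname(coef(reg)[1])
  if (slope >= 0) warn("non-negative Scatchard slope; data do not look like saturable binding")
  structure(list(slope = slope,
                 Kd = -1 / slope,
                 x_intercept = -intercept / slope,
                 r_squared = suppressWarnings(summary(reg)$r.squared),
                 n_points = length(bound), lm = reg),
            class = "scatchard_result")
}

#' Competition / stimulation profile against a competitor dose series
#'
#' Rank-based (distribution-free) monotone-association test of response
#' against competitor dose at alpha = 0.05.  When a trend is present and the
#' response spans at least a two-fold dynamic range, a four-parameter
#' logistic is fitted and the half-effect dose (EC50/IC50) reported.
#'
#' @param competitor_doses Competitor amounts (pmol); must include a
#'   zero-dose control.
#' @param responses Response at each dose (same length).
#' @param alpha Significance level of the trend test.
#' @return An object of class `competition_result`: `trend`
#'   (`"stimulation"`, `"inhibition"` or `"none"`), `rho`, `p_value`,
#'   `ec50` (NA when no logistic was fitted) and the fitted model.
#' @export
competition_profile <- function(competitor_doses, responses, alpha = 0.05) {
  if (length(competitor_doses) != length(responses)) {
    abort("doses and responses must have the same length")
  }
  if (length(unique(competitor_doses)) < 4) {
    abort("at least 4 distinct competitor doses are required")
  }
  if (!any(competitor_doses == 0)) {
    abort("a zero-dose (no-competitor) control is required")
  }
  ct <- suppressWarnings(cor.test(competitor_doses, responses,
                                  method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  trend <- if (ct$p.value < alpha && rho > 0) {
    "stimulation"
  } else if (ct$p.value < alpha && rho < 0) {
    "inhibition"
  } else {
    "none"
  }
  ec50 <- NA_real_
  fit <- NULL
  rng <- range(responses)
  if (trend != "none" && rng[1] > 0 && rng[2] / rng[1] >= 2) {
    df <- tibble(x = competitor_doses, y = responses)
    y0 <- responses[which.min(competitor_doses)][1]
    yinf <- responses[which.max(competitor_doses)][1]
    half <- (y0 + yinf) / 2
    pos <- competitor_doses[competitor_doses > 0]
    ec0 <- pos[which.min(abs(responses[competitor_doses > 0] - half))][1]
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ y0 + (yinf - y0) * x^h / (ec50^h + x^h), data = df,
        start = list(y0 = y0, yinf = yinf, ec50 = max(ec0, 1e-6), h = 1),
        lower = c(y0 = 0, yinf = 0, ec50 = 1e-9, h = 0.1),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) ec50 <- unname(coef(fit)["ec50"])
  }
  structure(list(trend = trend, rho = rho, p_value = ct$p.value,
                 ec50 = ec50, fit = fit),
            class = "competition_result")
}
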