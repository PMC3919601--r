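#' Configuration for simulated chemical-probing traces
#'
#' The trace simulator emulates per-primer-region integrated peak tables as
#' produced downstream of capillary-electrophoresis processing.  Background
#' (non-landmark) net reactivities are drawn from a log-normal distribution
#' -- empirical SHAPE reactivity distributions are right-skewed, and the
#' median < mean property this guarantees is what makes all five
#' discretization bins realizable.  The control channel is simulated as
#' low-level noise around `minus_channel_level`.
#'
#' @param n_positions Number of nucleotides in the region (>= 50).
#' @param region_start Reference rRNA position of the first nucleotide.
#' @param subunit `"18S"` or `"25S"`; landmarks are matched on it.
#' @param background_log_mean,background_log_sd Log-normal parameters of the
#'   background net-reactivity distribution (dimensionless units).
#' @param minus_channel_level Mean control-channel area; defaults to 5% of
#'   the background mean.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise (applied to background net values and to the control
#'   channel).
#' @param seed Integer seed; generation is a pure function of it.
#' @return A list of class `trace_sim_config`.
#' @export
trace_sim_config <- function(n_positions = 300L, region_start = 1L,
                             subunit = "25S",
                             background_log_mean = -1.0,
                             background_log_sd = 1.0,
                             minus_channel_level = NULL,
                             noise_cv = 0.05, seed = 1L) {
  if (n_positions < 50) abort("n_positions must be at least 50")
  if (noise_cv < 0) abort("noise_cv must be non-negative")
  if (background_log_sd < 0) abort("background_log_sd must be non-negative")
  bg_mean <- exp(background_log_mean + background_log_sd^2 / 2)
  structure(list(
    n_positions = as.integer(n_positions),
    region_start = as.integer(region_start),
    subunit = subunit,
    background_log_mean = background_log_mean,
    background_log_sd = background_log_sd,
    minus_channel_level = minus_channel_level %||% (0.05 * bg_mean),
    noise_cv = noise_cv,
    seed = as.integer(seed)
  ), class = "trace_sim_config")
}

# mean-1 multiplicative log-normal noise with coefficient of variation cv
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a peak table for a conformational state
#'
#' Generates the (+)reagent and (-)reagent integrated peak areas of one
#' primer region.  Background positions are drawn from the configured
#' right-skewed distribution; each landmark base targeted by the profile is
#' placed at the midpoint of its intended code's bin, computed from the
#' realized per-trace statistics (landmarks included, since per-trace
#' statistics make no exclusions).  Because placing landmarks perturbs the
#' statistics, placement is verified after recomputation and re-done once if
#' any code is off; a persistent mismatch is an error.  The generator's
#' contract is that running the full normalize-discretize pipeline on its
#' output recovers the profile's codes exactly.
#'
#' @param profile A [state_profile()].
#' @param config A [trace_sim_config()]; its `subunit` and window select
#'   which panel bases are simulated.
#' @param panel A [landmark_panel()].
#' @return A tibble of class `peak_table` with columns `region_id`,
#'   `subunit`, `position`, `nucleotide`, `plus_area`, `minus_area`;
#'   attributes record the state, seed, and intended landmark codes.
#' @export
simulate_peak_table <- function(profile, config = trace_sim_config(),
                                panel = landmark_panel()) {
  stopifnot(inherits(profile, "state_profile"),
            inherits(config, "trace_sim_config"))
  set.seed(config$seed)
  n <- config$n_positions
  positions <- config$region_start + seq_len(n) - 1L
  region_id <- paste0(config$subunit, ":", positions[1], "-", positions[n])

  in_window <- panel$subunit == config$subunit & panel$position %in% positions
  window_bases <- panel$base_id[in_window]
  targets <- profile$landmark_targets[names(profile$landmark_targets) %in% window_bases]
  # targets on this subunit but outside the window are a coordinate error
  stray <- names(profile$landmark_targets)[
    panel$subunit[match(names(profile$landmark_targets), panel$base_id)] ==
      config$subunit & !names(profile$landmark_targets) %in% window_bases]
  if (length(stray) > 0) {
    abort(paste0("landmark(s) outside the simulated region: ",
                 paste(stray, collapse = ", ")))
  }
  if (length(targets) > 0.1 * n) {
    abort("landmark count must not exceed 10% of n_positions")
  }

  net <- stats::rlnorm(n, config$background_log_mean, config$background_log_sd)
  net <- net * lnorm_noise(n, config$noise_cv)

  if (length(targets) > 0) {
    idx <- match(panel$position[match(names(targets), panel$base_id)],
                 positions)
    placed <- FALSE
    for (attempt in 1:2) {
      st <- trace_stats(net)
      net[idx] <- bin_midpoints(unname(targets), st)
      realized <- discretize_values(net, trace_stats(net))
      if (all(realized[idx] == unname(targets))) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(paste0("could not realize intended landmark codes in state '",
                   profile$state_name, "' after re-placement"))
    }
  }

  if (median(net) >= mean(net) && stats::sd(net) > 0) {
    warn("simulated background is not right-skewed (median >= mean); not all five reactivity bins are realizable")
  }

  minus <- config$minus_channel_level * lnorm_noise(n, config$noise_cv)
  out <- tibble(
    region_id = region_id,
    subunit = config$subunit,
    position = positions,
    nucleotide = sample(c("A", "C", "G", "U"), n, replace = TRUE),
    plus_area = net + minus,
    minus_area = minus
  )
  structure(out,
            state_name = profile$state_name,
            seed = config$seed,
            landmark_codes = targets,
            class = c("peak_table", class(as_tibble(out))))
}

# midpoint of each code's bin given trace statistics; the open top bin
# uses half an SD above its lower edge
bin_midpoints <- function(codes, st) {
  t0 <- st$median
  t1 <- st$mean
  t2 <- st$mean + st$sd
  t3 <- st$mean + 2 * st$sd
  mids <- c(t0 / 2, (t0 + t1) / 2, (t1 + t2) / 2, (t2 + t3) / 2,
            t3 + st$sd / 2)
  mids[codes + 1L]
}

#' Simulate per-subunit peak tables for one conformational state
#'
#' Convenience wrapper generating one trace per subunit represented in the
#' profile's targets, each spanning the panel's landmark range on that
#' subunit plus `pad` flanking nucleotides.
#'
#' @param profile A [state_profile()].
#' @param panel A [landmark_panel()].
#' @param seed Integer seed (per-subunit seeds are derived from it).
#' @param noise_cv,background_log_mean,background_log_sd,pad See
#'   [trace_sim_config()]; `pad` is the flank added on each side.
#' @return Named list of `peak_table` tibbles, one per subunit.
#' @export
simulate_state_traces <- function(profile, panel = landmark_panel(),
                                  seed = 1L, noise_cv = 0.05,
                                  background_log_mean = -1.0,
                                  background_log_sd = 1.0, pad = 20L) {
  subunits <- sort(unique(panel$subunit[panel$base_id %in%
                                          names(profile$landmark_targets)]))
  out <- lapply(seq_along(subunits), function(i) {
    su <- subunits[i]
    pos <- panel$position[panel$subunit == su]
    start <- max(1L, min(pos) - pad)
    cfg <- trace_sim_config(
      n_positions = max(pos) + pad - start + 1L,
      region_start = start, subunit = su,
      background_log_mean = background_log_mean,
      background_log_sd = background_log_sd,
      noise_cv = noise_cv,
      seed = seed * 13L + i
    )
    simulate_peak_table(profile, cfg, panel)
  })
  setNames(out, subunits)
}

#' Configuration for simulated equilibrium binding assays
#'
#' Emulates filter-binding dose series: serial dilutions of total ligand
#' incubated with a fixed amount of ribosomes, with the measured signal
#' reporting either the bound or the unbound fraction.  The noiseless signal
#' is the closed-form single-site ligand-depletion bound amount; noise is
#' multiplicative log-normal (scintillation-count heteroscedasticity).
#'
#' @param receptor_total Ribosomes per reaction (pmol).
#' @param ligand_totals Total-ligand dose vector (pmol); default eight
#'   two-fold serial dilutions of a 62.5 pmol top dose.
#' @param true_Kd,true_Bmax Ground-truth dissociation constant and maximal
#'   binding (pmol, reaction-volume units).
#' @param mode `"bound_measured"` or `"unbound_measured"`.
#' @param n_replicates Replicates per dose.
#' @param noise_cv Multiplicative noise CV.
#' @param seed Integer seed.
#' @param stoichiometry Binding sites per ribosome; single-site binding
#'   (one site, per the Scatchard analysis) is the locked default.
#' @return A list of class `binding_sim_config`.
#' @export
binding_sim_config <- function(receptor_total = 5,
                               ligand_totals = 62.5 / 2^(7:0),
                               true_Kd = 4, true_Bmax = 5,
                               mode = c("bound_measured", "unbound_measured"),
                               n_replicates = 4L, noise_cv = 0.05,
                               seed = 1L, stoichiometry = 1) {
  mode <- match.arg(mode)
  if (any(ligand_totals <= 0)) abort("ligand doses must be strictly positive")
  if (true_Kd <= 0) abort("true_Kd must be positive")
  if (true_Bmax <= 0 || true_Bmax > receptor_total * stoichiometry) {
    abort("true_Bmax must lie in (0, receptor_total * stoichiometry]")
  }
  if (noise_cv < 0) abort("noise_cv must be non-negative")
  structure(list(receptor_total = receptor_total,
                 ligand_totals = sort(ligand_totals),
                 true_Kd = true_Kd, true_Bmax = true_Bmax, mode = mode,
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "binding_sim_config")
}

#' Simulate a binding dose series
#'
#' @param config A [binding_sim_config()].
#' @return A tibble of class `binding_assay` with columns `dose_pmol`,
#'   `replicate`, `signal`; attributes carry the mode and ground truth.
#' @export
simulate_binding_assay <- function(config = binding_sim_config()) {
  stopifnot(inherits(config, "binding_sim_config"))
  set.seed(config$seed)
  grid <- tidyr::expand_grid(dose_pmol = config$ligand_totals,
                             replicate = seq_len(config$n_replicates))
  bound <- bound_closed_form(grid$dose_pmol, config$true_Kd, config$true_Bmax)
  clean <- if (config$mode == "bound_measured") bound else grid$dose_pmol - bound
  grid$signal <- clean * lnorm_noise(nrow(grid), config$noise_cv)
  structure(grid, mode = config$mode,
            truth = list(Kd = config$true_Kd, Bmax = config$true_Bmax),
            seed = config$seed,
            class = c("binding_assay", class(as_tibble(grid))))
}

#' Configuration for simulated single-turnover time courses
#'
#' @param true_kapp Apparent first-order rate (min^-1).
#' @param amplitude Product plateau (fraction or pmol).
#' @param timepoints Sampling times (min), strictly increasing.
#' @param noise_sd Additive Gaussian noise SD.
#' @param n_replicates Replicates per timepoint.
#' @param seed Integer seed.
#' @return A list of class `kinetics_sim_config`.
#' @export
kinetics_sim_config <- function(true_kapp = 0.5, amplitude = 1,
                                timepoints = c(0.5, 1, 2, 4, 6, 10, 15, 20),
                                noise_sd = 0.02, n_replicates = 1L,
                                seed = 1L) {
  if (true_kapp <= 0) abort("true_kapp must be positive")
  if (any(timepoints < 0)) abort("timepoints must be non-negative")
  if (is.unsorted(timepoints, strictly = TRUE)) {
    abort("timepoints must be strictly increasing")
  }
  structure(list(true_kapp = true_kapp, amplitude = amplitude,
                 timepoints = timepoints, noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "kinetics_sim_config")
}

#' Simulate a single-turnover peptidyltransfer time course
#'
#' Noiseless product formation follows `amplitude * (1 - exp(-kapp * t))`;
#' additive Gaussian noise of SD `noise_sd` is applied per observation.
#'
#' @param config A [kinetics_sim_config()].
#' @return A tibble of class `time_course` with columns `time_min`,
#'   `replicate`, `product`; attributes carry the ground truth.
#' @export
simulate_single_turnover <- function(config = kinetics_sim_config()) {
  stopifnot(inherits(config, "kinetics_sim_config"))
  set.seed(config$seed)
  grid <- tidyr::expand_grid(time_min = config$timepoints,
                             replicate = seq_len(config$n_replicates))
  clean <- config$amplitude * (1 - exp(-config$true_kapp * grid$time_min))
  grid$product <- clean + stats::rnorm(nrow(grid), 0, config$noise_sd)
  structure(grid,
            truth = list(kapp = config$true_kapp,
                         amplitude = config$amplitude),
            seed = config$seed,
            class = c("time_course", class(as_tibble(grid))))
}

#' Configuration for simulated dual-luciferase readings
#'
#' @param true_percent Ground-truth recoding rate (%) of the test reporter.
#' @param control_ratio_mean Firefly/renilla ratio of the control reporter.
#' @param renilla_scale Shared renilla luminescence scale.
#' @param noise_cv Multiplicative noise CV applied per luminescence reading.
#' @param n_replicates Replicate cultures per reporter (>= 2; assays are
#'   routinely done in quadruplicate).
#' @param seed Integer seed.
#' @return A list of class `luciferase_sim_config`.
#' @export
luciferase_sim_config <- function(true_percent = 2, control_ratio_mean = 0.5,
                                  renilla_scale = 1e5, noise_cv = 0.1,
                                  n_replicates = 4L, seed = 1L) {
  if (true_percent < 0) abort("true_percent must be non-negative")
  if (n_replicates < 2) abort("n_replicates must be at least 2")
  if (noise_cv < 0) abort("noise_cv must be non-negative")
  structure(list(true_percent = true_percent,
                 control_ratio_mean = control_ratio_mean,
                 renilla_scale = renilla_scale, noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "luciferase_sim_config")
}

#' Simulate paired dual-luciferase readings
#'
#' Emits raw firefly and renilla luminescence for a control reporter and a
#' test (recoding) reporter on a shared renilla scale.  The test reporter's
#' firefly signal is scaled by `true_percent / 100` relative to control.
#'
#' @param config A [luciferase_sim_config()].
#' @return A tibble of class `luciferase_readings` with columns `reporter`
#'   (`"control"`/`"test"`), `replicate`, `firefly`, `renilla`.
#' @export
simulate_luciferase <- function(config = luciferase_sim_config()) {
  stopifnot(inherits(config, "luciferase_sim_config"))
  set.seed(config$seed)
  n <- config$n_replicates
  make <- function(reporter, ratio) {
    renilla <- config$renilla_scale * lnorm_noise(n, config$noise_cv)
    firefly <- renilla * ratio * lnorm_noise(n, config$noise_cv)
    tibble(reporter = reporter, replicate = seq_len(n),
           firefly = firefly, renilla = renilla)
  }
  out <- dplyr::bind_rows(
    make("control", config$control_ratio_mean),
    make("test", config$control_ratio_mean * config$true_percent / 100)
  )
  structure(out, truth = list(percent = config$true_percent),
            seed = config$seed,
            class = c("luciferase_readings", class(as_tibble(out))))
}
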