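panel <- landmark_panel()
profiles <- default_state_profiles(panel)

test_that("every generator is a pure function of its seed", {
  cfg <- trace_sim_config(n_positions = 120, region_start = 2200,
                          seed = 9L)
  prof <- state_profile("mini", c(A2207 = 4L, U2258 = 0L), panel)
  expect_identical(simulate_peak_table(prof, cfg, panel),
                   simulate_peak_table(prof, cfg, panel))

  bc <- binding_sim_config(seed = 4L)
  expect_identical(simulate_binding_assay(bc), simulate_binding_assay(bc))

  kc <- kinetics_sim_config(seed = 4L)
  expect_identical(simulate_single_turnover(kc),
                   simulate_single_turnover(kc))

  lc <- luciferase_sim_config(seed = 4L)
  expect_identical(simulate_luciferase(lc), simulate_luciferase(lc))
})

test_that("pipeline recovers every intended landmark code for all packaged states", {
  for (seed in c(1L, 17L)) {
    for (nm in names(profiles)) {
      traces <- simulate_state_traces(profiles[[nm]], panel, seed = seed)
      codes <- lapply(traces, function(pk) process_peak_table(pk)$codes)
      prof <- codes_to_profile(codes, panel, nm)
      expected <- profiles[[nm]]$landmark_targets
      expect_identical(unname(prof$codes[names(expected)]),
                       unname(expected),
                       label = paste("state", nm, "seed", seed))
    }
  }
})

test_that("rotated-state trace discretizes to code 4 at A2207", {
  traces <- simulate_state_traces(profiles$rotated, panel, seed = 1L)
  codes <- process_peak_table(traces[["25S"]])$codes
  expect_equal(codes$code[codes$position == 2207], 4L)
})

test_that("simulated background is right-skewed and landmark-light", {
  pk <- simulate_state_traces(profiles$vacant, panel, seed = 3L)[["25S"]]
  net <- net_reactivity(pk)$net
  expect_lt(median(net), mean(net))
  expect_error(trace_sim_config(n_positions = 40), "at least 50")
})

test_that("degenerate constant background with no landmarks is well-defined", {
  cfg <- trace_sim_config(n_positions = 60, background_log_sd = 0,
                          noise_cv = 0, seed = 2L)
  pk <- simulate_peak_table(state_profile("empty", integer(0), panel),
                            cfg, panel)
  net <- net_reactivity(pk)$net
  expect_true(all(net == net[1]))
  tr <- normalize_by_region_median(net_reactivity(pk))
  expect_warning(codes <- discretize(tr), "not strictly increasing")
  expect_true(all(codes$code == 1L))
})

test_that("landmarks outside the simulated region raise an error", {
  cfg <- trace_sim_config(n_positions = 60, region_start = 2250,
                          subunit = "25S", seed = 1L)
  expect_error(
    simulate_peak_table(state_profile("far", c(A2207 = 4L), panel), cfg,
                        panel),
    "outside the simulated region")
})

test_that("noiseless binding simulation matches the depletion closed form", {
  cfg <- binding_sim_config(noise_cv = 0, n_replicates = 1,
                            true_Kd = 2, true_Bmax = 5,
                            ligand_totals = c(1, 2.5, 5, 10, 20))
  assay <- simulate_binding_assay(cfg)
  expect_equal(assay$signal, bound_closed_form(assay$dose_pmol, 2, 5),
               tolerance = 1e-12)
  expect_equal(assay$signal[assay$dose_pmol == 10], 3.7830,
               tolerance = 1e-4)

  cfgu <- binding_sim_config(noise_cv = 0, n_replicates = 1,
                             true_Kd = 2, true_Bmax = 5,
                             ligand_totals = c(1, 2.5, 5, 10, 20),
                             mode = "unbound_measured")
  un <- simulate_binding_assay(cfgu)
  expect_equal(un$signal[un$dose_pmol == 10], 10 - 3.7830,
               tolerance = 1e-4)

  # no-binding limit
  weak <- simulate_binding_assay(binding_sim_config(noise_cv = 0,
                                                    n_replicates = 1,
                                                    true_Kd = 1e9))
  expect_true(all(weak$signal < 1e-6))
  expect_error(binding_sim_config(ligand_totals = c(0, 1)), "positive")
  expect_error(binding_sim_config(true_Bmax = 10, receptor_total = 5),
               "receptor_total")
})

test_that("noiseless kinetics simulation matches the exponential closed form", {
  cfg <- kinetics_sim_config(true_kapp = 0.2, amplitude = 1,
                             timepoints = c(0.0, 2, log(2) / 0.2, 5, 30),
                             noise_sd = 0)
  tc <- simulate_single_turnover(cfg)
  expect_equal(tc$product[tc$time_min == 5], 1 - exp(-1), tolerance = 1e-12)
  expect_equal(tc$product[tc$time_min == 0], 0)
  expect_equal(tc$product[tc$time_min == log(2) / 0.2], 0.5,
               tolerance = 1e-12)
  expect_error(kinetics_sim_config(timepoints = c(2, 1)), "increasing")
})

test_that("noiseless luciferase readings encode the recoding rate exactly", {
  cfg <- luciferase_sim_config(true_percent = 10, control_ratio_mean = 0.5,
                               noise_cv = 0)
  r <- simulate_luciferase(cfg)
  test_r <- r[r$reporter == "test", ]
  ctl_r <- r[r$reporter == "control", ]
  expect_true(all(test_r$firefly / test_r$renilla == 0.05))
  expect_equal(recoding_percent(test_r, ctl_r)$percent, 10)

  ident <- simulate_luciferase(luciferase_sim_config(true_percent = 100,
                                                     noise_cv = 0))
  expect_equal(recoding_percent(ident[ident$reporter == "test", ],
                                ident[ident$reporter == "control", ])$percent,
               100)
  expect_error(luciferase_sim_config(n_replicates = 1), "at least 2")
})

test_that("noisy luciferase estimates are unbiased over seeds", {
  ests <- vapply(1:200, function(s) {
    r <- simulate_luciferase(luciferase_sim_config(true_percent = 2,
                                                   noise_cv = 0.1,
                                                   seed = s))
    recoding_percent(r[r$reporter == "test", ],
                     r[r$reporter == "control", ])$percent
  }, numeric(1))
  expect_lt(abs(mean(ests) - 2) / 2, 0.05)
})
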