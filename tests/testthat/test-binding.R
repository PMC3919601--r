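test_that("depletion closed form solves the equilibrium", {
  expect_equal(bound_closed_form(10, 2, 5), (17 - sqrt(89)) / 2,
               tolerance = 1e-12)
  expect_equal(bound_closed_form(0, 2, 5), 0)
  # stoichiometric limit: Kd -> 0+ gives min(Bmax, dose)
  expect_equal(bound_closed_form(10, 1e-12, 5), 5, tolerance = 1e-9)
  expect_equal(bound_closed_form(3, 1e-12, 5), 3, tolerance = 1e-9)
  expect_error(bound_closed_form(-1, 2, 5), "non-negative")
  expect_error(bound_closed_form(1, -2, 5), "positive")
})

test_that("closed form matches the numeric equilibrium root across 6 decades", {
  grid <- expand.grid(Kd = 10^seq(-3, 3, by = 1.5),
                      Bmax = 10^seq(-3, 3, by = 1.5),
                      dose = 10^seq(-3, 3, by = 1.5))
  for (i in seq_len(nrow(grid))) {
    b_cf <- bound_closed_form(grid$dose[i], grid$Kd[i], grid$Bmax[i])
    b_nm <- oracle_bound(grid$dose[i], grid$Kd[i], grid$Bmax[i])
    expect_lt(abs(b_cf - b_nm), 1e-9 + 1e-9 * abs(b_nm))
    expect_lte(b_cf, min(grid$Bmax[i], grid$dose[i]) + 1e-12)
  }
})

test_that("noise-free fits recover the truth exactly in both modes", {
  cfgb <- binding_sim_config(noise_cv = 0, n_replicates = 1)
  fb <- fit_binding(simulate_binding_assay(cfgb))
  expect_equal(fb$Kd, 4, tolerance = 1e-6)
  expect_equal(fb$Bmax, 5, tolerance = 1e-6)

  cfgu <- binding_sim_config(noise_cv = 0, n_replicates = 1,
                             mode = "unbound_measured")
  fu <- fit_binding(simulate_binding_assay(cfgu))
  expect_equal(fu$Kd, 4, tolerance = 1e-6)
  expect_equal(fu$Bmax, 5, tolerance = 1e-6)

  # mode duality: complementing the unbound signal reproduces the bound fit
  un <- simulate_binding_assay(cfgu)
  comp <- tibble::tibble(dose_pmol = un$dose_pmol, replicate = un$replicate,
                         signal = un$dose_pmol - un$signal)
  fc <- fit_binding(comp, mode = "bound_measured")
  expect_equal(fc$Kd, fu$Kd, tolerance = 1e-8)
  expect_equal(fc$Bmax, fu$Bmax, tolerance = 1e-8)

  # fitted curve respects the conservation bounds at every dose
  curve <- bound_closed_form(un$dose_pmol, fu$Kd, fu$Bmax)
  expect_true(all(curve <= pmin(fu$Bmax, un$dose_pmol) + 1e-9))

  expect_error(fit_binding(tibble::tibble(dose_pmol = c(1, 2, 4),
                                          signal = c(0.2, 0.4, 0.7))),
               "4 distinct doses")
})

test_that("noisy fits recover Kd without median bias", {
  ratios <- vapply(1:50, function(s) {
    fit_binding(simulate_binding_assay(binding_sim_config(seed = s)))$Kd
  }, numeric(1))
  expect_lt(abs(median(ratios) - 4) / 4, 0.1)
})

test_that("Kd fold-change combines fits with propagated error", {
  cfg <- binding_sim_config(noise_cv = 0, n_replicates = 1)
  f <- fit_binding(simulate_binding_assay(cfg))
  expect_equal(kd_fold_change(f, f)$ratio, 1)
  f8 <- fit_binding(simulate_binding_assay(
    binding_sim_config(noise_cv = 0, n_replicates = 1, true_Kd = 8)))
  fc <- kd_fold_change(f8, f)
  expect_equal(fc$ratio, 2, tolerance = 1e-5)
  expect_true(is.finite(fc$se) || is.na(fc$se))
})

test_that("Scatchard analysis is exact on noiseless single-site data", {
  d <- 62.5 / 2^(7:0)
  assay <- tibble::tibble(dose_pmol = d, replicate = 1L,
                          signal = bound_closed_form(d, 2, 5))
  sc <- scatchard(assay)
  expect_equal(sc$slope, -0.5, tolerance = 1e-9)
  expect_equal(sc$Kd, 2, tolerance = 1e-9)
  expect_equal(sc$x_intercept, 5, tolerance = 1e-9)
  expect_equal(sc$r_squared, 1, tolerance = 1e-9)

  # internal consistency with the nonlinear fit
  fit <- fit_binding(assay, mode = "bound_measured")
  expect_equal(sc$x_intercept, fit$Bmax, tolerance = 1e-5)
})

test_that("Scatchard detects curvature from a two-site mixture", {
  d <- 10^seq(-1, 2.5, length.out = 12)
  two_site <- bound_closed_form(d / 2, 1, 2.5) +
    bound_closed_form(d / 2, 50, 2.5)
  assay <- tibble::tibble(dose_pmol = d, replicate = 1L, signal = two_site)
  sc <- scatchard(assay)
  expect_lt(sc$r_squared, 0.99)
})

test_that("competition profiles detect monotone trends and recover IC50", {
  doses <- c(0, 31.25, 62.5, 125, 250, 500)
  up <- c(1, 1.2, 1.5, 1.9, 2.4, 3.0)
  expect_equal(competition_profile(doses, up)$trend, "stimulation")
  down <- rev(up)
  expect_equal(competition_profile(doses, down)$trend, "inhibition")
  expect_error(competition_profile(doses[-1], up[-1]), "zero-dose")

  # noiseless four-parameter logistic round-trips its IC50
  y <- 2 + (0.4 - 2) * doses^1.5 / (100^1.5 + doses^1.5)
  res <- competition_profile(doses, y)
  expect_equal(res$trend, "inhibition")
  expect_equal(res$ec50, 100, tolerance = 1e-6)
})
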